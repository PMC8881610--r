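## structure_model: reading/writing atomic models, selections, generic numbering

.WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")
.ION_RESID <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "NI", "CO",
                "CD", "BR", "IOD", "SO4", "PO4")

.guessElement <- function(elety, resid) {
  stripped <- gsub("^[0-9]+", "", elety)
  ele <- toupper(substr(stripped, 1, 1))
  # two-letter elements that occur in protein/lipid/ion records
  two <- toupper(substr(stripped, 1, 2))
  promote <- two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE") &
    nchar(stripped) > 1 & resid %in% c(.ION_RESID, "MSE")
  ele[promote] <- two[promote]
  ele
}

.newStructureModel <- function(atoms, sourceId = "") {
  defaults <- list(insert = "", o = 1, alt = "", het = FALSE,
                   label = NA_character_, region = NA_character_)
  for (nm in names(defaults))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  if (is.null(atoms$element))
    atoms$element <- .guessElement(atoms$elety, atoms$resid)
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms <- atoms[, .ATOM_COLS]
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, sourceId = sourceId)
}

#' Construct a StructureModel from an atom table
#'
#' Mostly used by the synthetic generators and tests; files are read
#' with [readStructure()].
#'
#' @param atoms data.frame with at least `chain`, `resno`, `resid`,
#'   `elety`, `x`, `y`, `z`; remaining columns get defaults.
#' @param sourceId identifier recorded on the model.
#' @return A [StructureModel-class].
#' @export
structureModel <- function(atoms, sourceId = "") .newStructureModel(atoms, sourceId)

.residKey <- function(a) paste(a$chain, a$resno, a$insert, sep = "|")
.atomKey <- function(a) paste(a$chain, a$resno, a$insert, a$elety, sep = "|")

# keep the highest-occupancy altloc conformer; ties -> lexicographically
# first altloc id (deterministic)
.resolveAltlocs <- function(atoms) {
  if (!any(nzchar(atoms$alt))) return(atoms)
  idx <- seq_len(nrow(atoms))
  ord <- order(.atomKey(atoms), -atoms$o, atoms$alt)
  atoms <- atoms[ord, ]
  idx <- idx[ord]
  dup <- duplicated(.atomKey(atoms))
  atoms <- atoms[!dup, ]
  atoms$alt <- ""
  atoms[order(idx[!dup]), , drop = FALSE]
}

#' Read an atomic model from PDB or mmCIF
#'
#' Retains all atoms of the first model, including nonstandard residues
#' (Aib, acylated lysines, gamma-Glu/OEG linker components) which the
#' lipidation analysis depends on. Alternate locations are resolved to
#' the highest-occupancy conformer (ties: lexicographically first
#' altloc id). Waters and common ions are excluded unless
#' `keepWaters = TRUE`. Coordinates are Angstrom throughout.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param keepWaters retain waters and monoatomic ions.
#' @return A [StructureModel-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif"),
                          keepWaters = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path, verbose = FALSE,
                                           rm.alt = FALSE)
      else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE,
                           rm.alt = FALSE)),
    error = function(e) stop("cannot parse ", path, " as ", toupper(format),
                             ": ", conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty model in ", path)
  if (!is.null(parsed$xyz) && is.matrix(parsed$xyz) && nrow(parsed$xyz) > 1L)
    message("multi-model file: using model 1 of ", nrow(parsed$xyz))
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    element = if (!is.null(at$elesy) && any(nzchar(at$elesy) & !is.na(at$elesy)))
      toupper(ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                     .guessElement(at$elety, at$resid), at$elesy))
      else .guessElement(at$elety, at$resid),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  if (!keepWaters)
    atoms <- atoms[!(atoms$resid %in% .WATER_RESID |
                       (atoms$het & atoms$resid %in% .ION_RESID)), ]
  if (nrow(atoms) == 0L) stop("empty model in ", path)
  atoms <- .resolveAltlocs(atoms)
  .newStructureModel(atoms, sourceId = basename(path))
}

#' Write a model to PDB format
#'
#' @param model a [StructureModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(model, path) {
  a <- model@atoms
  bio3d::write.pdb(file = path,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   resid = a$resid, chain = a$chain, resno = a$resno,
                   insert = ifelse(nzchar(a$insert), a$insert, ""),
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   o = a$o, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

## ---- selection -------------------------------------------------------------

.REGION_ALIASES <- list(TMD = paste0("TM", 1:7))

.parseRanges <- function(txt) {
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  unlist(lapply(parts, function(p) {
    p <- trimws(p)
    if (grepl("^-?[0-9]+[-:]-?[0-9]+$", p)) {
      ends <- as.integer(strsplit(p, "[-:]")[[1]][1:2])
      seq(ends[1], ends[2])
    } else as.integer(p)
  }))
}

#' Select a sub-model
#'
#' Selection expressions are clauses joined with `and`; each clause is
#' a keyword followed by comma-separated values:
#' `chain`, `resno`/`resi` (ranges as `194-211` or `194:211`),
#' `name`/`elety`, `resid`, `region` (after [applyNumbering()];
#' `TMD` expands to TM1..TM7), `label` (generic labels / peptide
#' positions), `hetero` (`yes`/`no`). Example:
#' `"chain R and resno 194-211 and name CA"`. Alternatively pass the
#' same keywords as named arguments. An empty selection is allowed,
#' but an unknown chain, region or label raises a selection error
#' naming the token. Selection is idempotent.
#'
#' @param model a [StructureModel-class].
#' @param expr selection expression (character), or missing.
#' @param ... named selection arguments (`chain=`, `resno=`, `elety=`,
#'   `resid=`, `region=`, `label=`, `hetero=`).
#' @return A [StructureModel-class] preserving all record fields.
#' @export
selectAtoms <- function(model, expr, ...) {
  stopifnot(is(model, "StructureModel"))
  args <- list(...)
  if (!missing(expr) && is.character(expr)) {
    for (clause in strsplit(expr, "\\s+and\\s+")[[1]]) {
      clause <- trimws(clause)
      if (!nzchar(clause)) next
      m <- regmatches(clause, regexec("^(\\S+)\\s+(.*)$", clause))[[1]]
      if (length(m) != 3L) stop("cannot parse selection clause: '", clause, "'")
      args[[m[2]]] <- m[3]
    }
  }
  a <- model@atoms
  keep <- rep(TRUE, nrow(a))
  for (key in names(args)) {
    val <- args[[key]]
    if (is.character(val) && length(val) == 1L && key %in% c("chain", "name",
        "elety", "resid", "region", "label"))
      val <- trimws(strsplit(val, ",")[[1]])
    keep <- keep & switch(key,
      chain = {
        unknown <- setdiff(val, unique(a$chain))
        if (length(unknown))
          stop("selection error: unknown chain '",
               paste(unknown, collapse = "', '"), "'")
        a$chain %in% val
      },
      resno = , resi = {
        if (is.character(val)) val <- .parseRanges(paste(val, collapse = ","))
        a$resno %in% val
      },
      name = , elety = a$elety %in% val,
      resid = a$resid %in% val,
      region = {
        val <- unlist(lapply(val, function(v)
          if (!is.null(.REGION_ALIASES[[v]])) .REGION_ALIASES[[v]] else v))
        known <- unique(stats::na.omit(a$region))
        unknown <- setdiff(val, known)
        if (length(unknown) == length(val))
          stop("selection error: unknown region '",
               paste(unknown, collapse = "', '"),
               "' (did you call applyNumbering?)")
        !is.na(a$region) & a$region %in% val
      },
      label = {
        unknown <- setdiff(val, unique(stats::na.omit(a$label)))
        if (length(unknown))
          stop("selection error: unknown label '",
               paste(unknown, collapse = "', '"), "'")
        !is.na(a$label) & a$label %in% val
      },
      hetero = if (identical(val, "yes") || isTRUE(val)) a$het else !a$het,
      stop("selection error: unknown keyword '", key, "'"))
  }
  out <- model
  out@atoms <- a[keep, , drop = FALSE]
  rownames(out@atoms) <- NULL
  out
}

## ---- generic numbering -----------------------------------------------------

#' Read a residue-numbering map from TSV
#'
#' Expected columns: `chain`, `auth_seq`, `res_name`, `generic_label`,
#' `region`. `generic_label` may be a class B generic position
#' (`"6.35b"`), a peptide position (`"27P"`), or empty.
#'
#' @param path TSV file path.
#' @param receptorName optional receptor name recorded on the map.
#' @return A [NumberingMap-class].
#' @export
readNumberingMap <- function(path, receptorName = "") {
  e <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(auth_seq = "integer"))
  for (col in c("chain", "res_name", "generic_label", "region")) {
    e[[col]] <- as.character(e[[col]])
    e[[col]][is.na(e[[col]])] <- ""
  }
  new("NumberingMap", entries = e, receptorName = receptorName)
}

#' Construct a NumberingMap in code
#'
#' @param chain,auth_seq,res_name,generic_label,region vectors recycled
#'   to a common length.
#' @param receptorName optional receptor name.
#' @return A [NumberingMap-class].
#' @export
numberingMap <- function(chain, auth_seq, res_name = "", generic_label = "",
                         region = "", receptorName = "") {
  n <- max(length(chain), length(auth_seq))
  e <- data.frame(chain = rep_len(chain, n),
                  auth_seq = rep_len(as.integer(auth_seq), n),
                  res_name = rep_len(res_name, n),
                  generic_label = rep_len(generic_label, n),
                  region = rep_len(region, n), stringsAsFactors = FALSE)
  new("NumberingMap", entries = e, receptorName = receptorName)
}

#' Attach generic residue labels to a model
#'
#' Every mapped residue carries its generic label (`x.yyb`, region, or
#' peptide position `nP`); unmapped residues remain addressable by
#' chain/residue number. Map entries pointing at residues absent from
#' the model produce a warning, not an error. Coordinates and atom
#' counts are never changed.
#'
#' @param model a [StructureModel-class].
#' @param map a [NumberingMap-class].
#' @return The labelled [StructureModel-class].
#' @export
applyNumbering <- function(model, map) {
  stopifnot(is(model, "StructureModel"), is(map, "NumberingMap"))
  e <- map@entries
  if (nrow(e) == 0L) return(model)
  a <- model@atoms
  mkey <- paste(e$chain, e$auth_seq, sep = "|")
  akey <- paste(a$chain, a$resno, sep = "|")
  hit <- match(akey, mkey)
  lab <- e$generic_label[hit]
  reg <- e$region[hit]
  a$label <- ifelse(!is.na(hit) & nzchar(lab), lab, a$label)
  a$region <- ifelse(!is.na(hit) & nzchar(reg), reg, a$region)
  absent <- setdiff(mkey, akey)
  if (length(absent))
    warning("numbering map entries for residues absent from model: ",
            paste(absent, collapse = ", "))
  rn <- e$res_name[hit]
  mismatch <- !is.na(hit) & !is.na(rn) & nzchar(rn) & a$resid != rn
  if (any(mismatch))
    warning("residue name mismatch between map and model at ",
            paste(unique(akey[mismatch]), collapse = ", "))
  model@atoms <- a
  model
}

#' Count modeled residues in a chain
#'
#' A residue counts as modeled when at least one of its atoms is
#' present.
#'
#' @param model a [StructureModel-class].
#' @param chain chain identifier.
#' @return Integer residue count.
#' @export
modeledResidueCount <- function(model, chain) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  if (!chain %in% a$chain)
    stop("selection error: unknown chain '", chain, "'")
  length(unique(.residKey(a[a$chain == chain, ])))
}

#' @describeIn StructureModel-class number of atoms
#' @param x a StructureModel
#' @export
setMethod("length", "StructureModel", function(x) nrow(x@atoms))

#' Atom table accessor
#' @param x a [StructureModel-class]
#' @return the atom data.frame
#' @export
atoms <- function(x) x@atoms

#' Coordinate matrix accessor
#' @param x a [StructureModel-class]
#' @return Nx3 matrix of coordinates (Angstrom)
#' @export
coords <- function(x) as.matrix(x@atoms[, c("x", "y", "z")])

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel", if (nzchar(object@sourceId))
    paste0("[", object@sourceId, "]"), "\n")
  cat(" ", nrow(a), "atoms,", length(unique(.residKey(a))), "residues,",
      "chains:", paste(sort(unique(a$chain)), collapse = " "), "\n")
  if (any(!is.na(a$label)))
    cat("  generic labels attached (", sum(!is.na(a$label)), " atoms )\n",
        sep = "")
  invisible(object)
})

setMethod("show", "NumberingMap", function(object) {
  cat("NumberingMap", if (nzchar(object@receptorName))
    paste0("[", object@receptorName, "]"),
    ":", nrow(object@entries), "entries\n")
  invisible(object)
})
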