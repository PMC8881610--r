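#' @import methods
NULL

.ATOM_COLS <- c("chain", "resno", "insert", "resid", "elety", "element",
                "x", "y", "z", "o", "alt", "het", "label", "region")

#' StructureModel: an atomic model with optional generic residue labels
#'
#' A light container for one atomic model. Atoms are stored in a
#' data frame with one row per atom and columns `chain`, `resno`
#' (author residue number), `insert` (insertion code, "" if none),
#' `resid` (3-letter residue code), `elety` (atom name, e.g. `CA`),
#' `element`, `x`/`y`/`z` (coordinates in Angstrom), `o` (occupancy),
#' `alt` (alternate-location id, "" after resolution), `het`
#' (HETATM flag), and — once [applyNumbering()] has been called —
#' `label` (class B generic label such as `"6.35b"` or a peptide
#' position such as `"27P"`) and `region` (TM1..TM7, H8, ECL1-3,
#' ICL1-3, ECD).
#'
#' @slot atoms data.frame of atom records (see Details).
#' @slot sourceId character; file name or accession the model came from.
#' @seealso [readStructure()], [selectAtoms()], [applyNumbering()]
#' @export
setClass("StructureModel",
         representation(atoms = "data.frame", sourceId = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  msg <- character()
  missing <- setdiff(.ATOM_COLS, names(a))
  if (length(missing))
    msg <- c(msg, paste("missing atom columns:", paste(missing, collapse = ", ")))
  if (!length(msg) && nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      msg <- c(msg, "non-finite coordinates")
    if (!all(a$o >= 0 & a$o <= 1, na.rm = TRUE))
      msg <- c(msg, "occupancy outside [0, 1]")
    if (any(!nzchar(a$element)))
      msg <- c(msg, "empty element symbol")
  }
  if (length(msg)) msg else TRUE
})

#' NumberingMap: author residue numbers to class B generic labels
#'
#' Maps author residue numbers of one receptor chain to class B
#' generic labels (`x.yyb`, Wootten scheme) and structural regions
#' (TM1..TM7, H8, ECL1-3, ICL1-3, ECD). Read from TSV with
#' [readNumberingMap()].
#'
#' @slot entries data.frame with columns `chain`, `auth_seq`,
#'   `res_name`, `generic_label`, `region`.
#' @slot receptorName character, e.g. `"GIPR"`.
#' @export
setClass("NumberingMap",
         representation(entries = "data.frame", receptorName = "character"))

setValidity("NumberingMap", function(object) {
  e <- object@entries
  need <- c("chain", "auth_seq", "res_name", "generic_label", "region")
  missing <- setdiff(need, names(e))
  if (length(missing))
    return(paste("missing map columns:", paste(missing, collapse = ", ")))
  gen <- !is.na(e$generic_label) & grepl("^[0-9]\\.[0-9]{2}b$", e$generic_label)
  if (anyDuplicated(e$generic_label[gen]))
    return("generic labels must be unique within one receptor")
  # a TM generic label must sit in the matching helix region
  tm <- gen & grepl("^TM[1-7]$", e$region)
  if (any(tm & e$region != paste0("TM", substr(e$generic_label, 1, 1))))
    return("TM generic label inconsistent with its region tag")
  TRUE
})

#' RigidTransform: proper rotation plus translation
#'
#' Maps coordinates of the mobile model onto the reference frame as
#' `x_aligned = x %*% t(rotation) + translation` (row-vector
#' convention, Angstrom).
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric, Angstrom.
#' @export
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (abs(det(R) - 1) > 1e-9) return("rotation determinant must be +1")
  if (max(abs(R %*% t(R) - diag(3))) > 1e-9) return("rotation not orthonormal")
  if (length(object@translation) != 3L) return("translation must be length 3")
  TRUE
})

#' SuperposeResult: outcome of a rigid-body superposition
#'
#' @slot transform [RigidTransform-class] mapping model b onto model a.
#' @slot rmsd root-mean-square deviation over the fitted atoms, Angstrom.
#' @slot nPairs number of paired atoms used in the fit.
#' @slot pairing data.frame recording the residue/atom correspondence
#'   used (may have zero rows for raw coordinate fits).
#' @export
setClass("SuperposeResult",
         representation(transform = "RigidTransform", rmsd = "numeric",
                        nPairs = "integer", pairing = "data.frame"))

setValidity("SuperposeResult", function(object) {
  if (object@rmsd < 0) return("rmsd must be >= 0")
  if (object@nPairs < 3L) return("at least 3 paired atoms required")
  TRUE
})

#' AreaResult: per-atom solvent-accessible surface area
#'
#' @slot perAtom numeric vector, one SASA value (Angstrom^2) per atom.
#' @slot total sum of `perAtom`.
#' @slot probeRadius probe sphere radius, Angstrom.
#' @slot nPoints number of quadrature points per atom sphere.
#' @export
setClass("AreaResult",
         representation(perAtom = "numeric", total = "numeric",
                        probeRadius = "numeric", nPoints = "integer"))

setValidity("AreaResult", function(object) {
  if (any(object@perAtom < -1e-9)) return("per-atom areas must be >= 0")
  if (abs(object@total - sum(object@perAtom)) > 1e-6)
    return("total must equal sum of per-atom areas")
  TRUE
})

#' ChemistryAssignment: interaction-capable groups of a model
#'
#' @slot donors data.frame of hydrogen-bond donor heavy atoms with
#'   their covalent antecedent atom name.
#' @slot acceptors data.frame of acceptor heavy atoms.
#' @slot cations list of cationic groups (each: residue key, atom set,
#'   charged atom names, group center).
#' @slot anions list of anionic groups (each: residue key, atom set,
#'   charged oxygen names).
#' @slot rings list of aromatic rings (each: residue key, 5 or 6 ring
#'   atoms, centroid, unit normal).
#' @slot apolar data.frame of apolar carbon/sulfur atoms.
#' @export
setClass("ChemistryAssignment",
         representation(donors = "data.frame", acceptors = "data.frame",
                        cations = "list", anions = "list",
                        rings = "list", apolar = "data.frame"))

#' FingerprintString: per-peptide-position interaction roll-up
#'
#' Ordered entries for peptide positions `1..peptideLength`; each
#' entry is a data.frame of `(type, receptor_label)` pairs (zero rows
#' for positions with no contacts, which are retained).
#'
#' @slot positions list of data.frames, one per peptide position.
#' @slot complexId character identifier of the complex.
#' @export
setClass("FingerprintString",
         representation(positions = "list", complexId = "character"))

setValidity("FingerprintString", function(object) {
  ok <- vapply(object@positions, function(p)
    is.data.frame(p) && all(c("type", "receptor_label") %in% names(p)), TRUE)
  if (!all(ok)) return("each position must be a (type, receptor_label) data.frame")
  TRUE
})

#' FingerprintDiff: gained/lost/conserved contacts between two fingerprints
#'
#' @slot perPosition list; per position a list with data.frames
#'   `gained`, `lost`, `conserved`.
#' @slot idA,idB complex identifiers of the compared fingerprints.
#' @export
setClass("FingerprintDiff",
         representation(perPosition = "list", idA = "character",
                        idB = "character"))

#' LogisticFit: three-parameter logistic concentration-response fit
#'
#' Model: `response = bottom + (top - bottom) / (1 + 10^(-(pEC50 + log10(conc))))`
#' with Hill slope fixed at 1.
#'
#' @slot bottom,top response units.
#' @slot pec50 -log10(EC50 in molar).
#' @slot se named numeric standard errors (bottom, top, pec50).
#' @slot converged logical convergence flag.
#' @slot extrapolated logical; TRUE when the fitted EC50 lies outside
#'   the tested concentration range by more than two orders of magnitude.
#' @slot nObs number of fitted points.
#' @export
setClass("LogisticFit",
         representation(bottom = "numeric", top = "numeric", pec50 = "numeric",
                        se = "numeric", converged = "logical",
                        extrapolated = "logical", nObs = "integer"))
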