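## cli_report: orchestrate end-to-end comparisons from a single config

.readConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run an end-to-end structural comparison from a config
#'
#' Loads each declared complex (model file, peptide/receptor chains,
#' optional numbering map), computes its interaction fingerprint, and
#' for every declared pair computes C-alpha RMSD over the frame
#' selection, probe-atom displacements, peptide-receptor buried and
#' interface areas (both delta-SASA conventions, side by side) and
#' the fingerprint diff. Writes per-complex fingerprint TSVs,
#' pairwise diff TSVs, a metrics JSON and a log of the criteria used.
#' Outputs carry no timestamps, so re-running the same config gives
#' byte-identical files. Errors in one entry are recorded and the
#' remaining entries still run.
#'
#' Config (YAML or JSON file, or an equivalent list): `output_dir`;
#' `complexes`: list of `{id, path, peptide_chain, receptor_chain,
#' numbering_map (optional), peptide_length (optional)}`;
#' `pairs`: list of `{a, b, frame (optional selection), probes
#' (optional atom addresses)}`; `criteria`: optional
#' [contactCriteria()] overrides; `sasa_points`: optional quadrature
#' density.
#'
#' @param config file path or list (see Details).
#' @return Invisibly, a list with `metrics`, `fingerprints`, `errors`
#'   and `exit_code` (0 clean, 2 when any entry failed).
#' @export
runComparison <- function(config) {
  cfg <- .readConfig(config)
  outDir <- cfg$output_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  criteria <- do.call(contactCriteria, as.list(cfg$criteria %||% list()))
  nPoints <- cfg$sasa_points %||% 1920L
  errors <- list()
  note <- function(id, e) {
    errors[[id]] <<- conditionMessage(e)
    message("[", id, "] ERROR: ", conditionMessage(e))
    NULL
  }
  asEntries <- function(x) {
    # yaml gives a list of lists; json/simplifyVector may give a data.frame
    if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i)
      as.list(x[i, , drop = FALSE])) else x
  }
  complexes <- list()
  fingerprints <- list()
  for (entry in asEntries(cfg$complexes)) {
    id <- entry$id
    complexes[[id]] <- tryCatch({
      model <- readStructure(entry$path)
      if (!is.null(entry$numbering_map) && !is.na(entry$numbering_map))
        model <- applyNumbering(model, readNumberingMap(entry$numbering_map))
      list(model = model, entry = entry)
    }, error = function(e) note(id, e))
    if (is.null(complexes[[id]])) next
    fingerprints[[id]] <- tryCatch({
      model <- complexes[[id]]$model
      ct <- detectContacts(model,
                           paste("chain", entry$peptide_chain),
                           paste("chain", entry$receptor_chain), criteria)
      len <- entry$peptide_length %||%
        modeledResidueCount(model, entry$peptide_chain)
      fp <- buildFingerprint(ct, len, complexId = id)
      .writeTsv(ct[, setdiff(names(ct), "dominant")],
                file.path(outDir, paste0(id, "_contacts.tsv")))
      .writeTsv(as.data.frame(fp),
                file.path(outDir, paste0(id, "_fingerprint.tsv")))
      fp
    }, error = function(e) note(paste0(id, ":fingerprint"), e))
  }
  metrics <- list()
  for (pair in asEntries(cfg$pairs)) {
    pid <- paste0(pair$a, "_vs_", pair$b)
    metrics[[pid]] <- tryCatch({
      ca <- complexes[[pair$a]]; cb <- complexes[[pair$b]]
      if (is.null(ca) || is.null(cb))
        stop("pair references a complex that failed to load")
      frame <- pair$frame %||%
        paste("chain", ca$entry$receptor_chain, "and name CA")
      fit <- tryCatch(.frameFit(ca$model, cb$model, frame),
                      error = function(e) stop("frame fit failed: ",
                                               conditionMessage(e)))
      m <- list(rmsd = fit@rmsd, n_pairs = fit@nPairs)
      for (probe in unlist(pair$probes))
        m[[paste0("displacement_", gsub(":", "_", probe))]] <-
          as.numeric(displacement(ca$model, cb$model, frame, probe))
      for (side in c("a", "b")) {
        cx <- if (side == "a") ca else cb
        bsa <- buriedSurfaceArea(cx$model,
                                 paste("chain", cx$entry$peptide_chain),
                                 paste("chain", cx$entry$receptor_chain),
                                 nPoints = nPoints)
        m[[paste0("buried_area_", side)]] <- bsa
        m[[paste0("interface_area_half_", side)]] <- bsa / 2
      }
      if (!is.null(fingerprints[[pair$a]]) &&
          !is.null(fingerprints[[pair$b]])) {
        d <- diffFingerprints(fingerprints[[pair$a]], fingerprints[[pair$b]])
        .writeTsv(as.data.frame(d),
                  file.path(outDir, paste0(pid, "_diff.tsv")))
        s <- summary(d)
        m$fingerprint_gained <- unname(s["gained"])
        m$fingerprint_lost <- unname(s["lost"])
        m$fingerprint_conserved <- unname(s["conserved"])
      }
      m
    }, error = function(e) note(pid, e))
  }
  report <- list(criteria = criteria, sasa_points = nPoints,
                 metrics = metrics,
                 errors = if (length(errors)) errors else NULL)
  jsonlite::write_json(report, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(metrics = metrics, fingerprints = fingerprints,
                 errors = errors,
                 exit_code = if (length(errors)) 2L else 0L))
}

#' Regression against deposited peptide-receptor complex structures
#'
#' Recomputes the published structural metrics from locally cached
#' coordinate files of the deposited complexes (tirzepatide- and
#' peptide 20-bound GIPR/GLP-1R/GCGR and the reference GIP/GLP-1/GCG
#' complexes). The tool never downloads: `cacheDir` must already hold
#' `<id>.pdb` or `<id>.cif` files fetched once by the user, e.g. from
#' the PDB. Returns the recomputed receptor C-alpha RMSDs, peptide
#' C-terminal tip displacements, the ECL1 glycine offset and the
#' peptide/ECL1 and ICL2/G-alpha-s interface areas (both delta-SASA
#' conventions), plus the modeled peptide length.
#'
#' @param cacheDir directory holding coordinate files named by
#'   accession (lower or upper case).
#' @param nPoints SASA quadrature density.
#' @return Named list of metrics.
#' @export
depositedRegression <- function(cacheDir, nPoints = 1920L) {
  find <- function(id) {
    for (ext in c(".pdb", ".cif", ".pdb.gz", ".cif.gz"))
      for (case in c(tolower(id), toupper(id))) {
        p <- file.path(cacheDir, paste0(case, ext))
        if (file.exists(p)) return(p)
      }
    stop("structure cache miss: no coordinate file for ", id, " in ",
         cacheDir)
  }
  load1 <- function(id) readStructure(find(id))
  tzpGipr <- load1("7fiy"); gipGipr <- load1("7dty")
  tzpGlp1r <- load1("7fim"); glp1Glp1r <- load1("6x18")
  p20Gipr <- load1("7fin"); p20Gcgr <- load1("7v35"); p20Glp1r <- load1("7vbh")
  # receptor chain is R in these depositions; peptide chain P
  out <- list(
    rmsd_tzp_gipr_vs_gip_gipr = caRmsd(tzpGipr, gipGipr, chainA = "R")@rmsd,
    rmsd_tzp_glp1r_vs_glp1 = caRmsd(tzpGlp1r, glp1Glp1r, chainA = "R")@rmsd,
    tip_shift_p20_gipr_vs_gip = as.numeric(
      displacement(p20Gipr, gipGipr, "chain R and name CA", "P:27:CA")),
    tip_shift_tzp_gipr_vs_glp1r = as.numeric(
      displacement(tzpGipr, tzpGlp1r, "chain R and name CA", "P:27:CA")),
    tip_shift_p20_gipr_vs_gcgr = as.numeric(
      displacement(p20Gipr, p20Gcgr, "chain R and name CA", "P:27:CA")),
    ecl1_gly_offset = as.numeric(
      crossAtomDistance(p20Gipr, p20Gcgr, "chain R and name CA",
                        "R:202:CA", "R:207:CA")),
    bsa_gip_ecl1 = buriedSurfaceArea(gipGipr, "chain P",
                                     "chain R and resno 194-211",
                                     nPoints = nPoints),
    bsa_p20_ecl1 = buriedSurfaceArea(p20Gipr, "chain P",
                                     "chain R and resno 194-211",
                                     nPoints = nPoints),
    modeled_tzp_length = modeledResidueCount(tzpGipr, "P"))
  out
}
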