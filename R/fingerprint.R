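## fingerprint strings: per-peptide-position interaction roll-up and diffs

.contactPosition <- function(ct) {
  # peptide position: the nP label when attached, else the author number
  pos <- suppressWarnings(as.integer(sub("P$", "", ct$pep_label)))
  ifelse(!is.na(pos) & grepl("^[0-9]+P$", ct$pep_label), pos, ct$pep_resno)
}

.receptorLabel <- function(ct) {
  ifelse(nzchar(ct$rec_label), ct$rec_label,
         paste0(ct$rec_resid, ct$rec_resno))
}

#' Build a per-position interaction fingerprint string
#'
#' Rolls typed contacts up into one ordered entry per peptide position
#' `1..peptideLength`; each entry is the set of
#' `(interaction type, receptor residue label)` pairs at that
#' position. Positions with no contacts are present and empty (the
#' "white circles" of a fingerprint diagram). Ordering is
#' deterministic: position, then receptor label, then type — so
#' identical inputs give byte-identical fingerprints.
#'
#' @param contacts data.frame from [detectContacts()].
#' @param peptideLength number of peptide positions.
#' @param complexId identifier recorded on the fingerprint.
#' @param dominantOnly use only the dominant contact per residue pair.
#' @return A [FingerprintString-class].
#' @export
buildFingerprint <- function(contacts, peptideLength, complexId = "",
                             dominantOnly = FALSE) {
  stopifnot(peptideLength >= 1)
  if (dominantOnly && nrow(contacts)) contacts <- contacts[contacts$dominant, ]
  empty <- data.frame(type = character(), receptor_label = character(),
                      stringsAsFactors = FALSE)
  positions <- rep(list(empty), peptideLength)
  if (nrow(contacts)) {
    pos <- .contactPosition(contacts)
    if (any(pos < 1 | pos > peptideLength))
      stop("consistency error: contact at peptide position ",
           paste(unique(pos[pos < 1 | pos > peptideLength]), collapse = ", "),
           " outside 1..", peptideLength)
    lab <- .receptorLabel(contacts)
    for (p in unique(pos)) {
      sub <- unique(data.frame(type = contacts$type[pos == p],
                               receptor_label = lab[pos == p],
                               stringsAsFactors = FALSE))
      sub <- sub[order(sub$receptor_label, sub$type), , drop = FALSE]
      rownames(sub) <- NULL
      positions[[p]] <- sub
    }
  }
  new("FingerprintString", positions = positions, complexId = complexId)
}

#' @describeIn FingerprintString-class number of peptide positions
#' @param x a FingerprintString
#' @export
setMethod("length", "FingerprintString", function(x) length(x@positions))

#' Flatten a fingerprint to a data.frame
#'
#' @param x a [FingerprintString-class].
#' @param ... ignored.
#' @return data.frame with columns position, type, receptor_label
#'   (positions with no contacts are omitted here; they are retained
#'   in the object itself).
#' @export
setMethod("as.data.frame", "FingerprintString", function(x, ...) {
  rows <- lapply(seq_along(x@positions), function(p) {
    e <- x@positions[[p]]
    if (!nrow(e)) return(NULL)
    cbind(data.frame(position = p), e)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(position = integer(), type = character(),
                      receptor_label = character())
  rownames(out) <- NULL
  out
})

setMethod("show", "FingerprintString", function(object) {
  cat("FingerprintString", if (nzchar(object@complexId))
    paste0("[", object@complexId, "]"), ":", length(object@positions),
    "positions,", sum(vapply(object@positions, nrow, 0L)), "typed contacts\n")
  occupied <- which(vapply(object@positions, nrow, 0L) > 0)
  for (p in utils::head(occupied, 8)) {
    e <- object@positions[[p]]
    cat(sprintf("  %2d: %s\n", p,
                paste(paste0(e$type, "(", e$receptor_label, ")"),
                      collapse = " ")))
  }
  if (length(occupied) > 8) cat("  ...\n")
  invisible(object)
})

#' Difference between two fingerprints
#'
#' Per-position set differences: contacts `lost` (present in A,
#' absent in B), `gained` (present in B, absent in A) and `conserved`
#' — the machinery behind statements like "E3P-Q eliminated the salt
#' bridge with R190 (2.60b)". Peptides of different register are
#' aligned with `positionMap` (named integer vector mapping positions
#' of A to positions of B); without a map the two fingerprints must
#' have equal length.
#'
#' @param fpA,fpB [FingerprintString-class] objects.
#' @param positionMap optional named integer vector `A position -> B
#'   position`; unmapped positions are compared index-to-index.
#' @return A [FingerprintDiff-class].
#' @export
diffFingerprints <- function(fpA, fpB, positionMap = NULL) {
  if (is.null(positionMap) && length(fpA) != length(fpB))
    stop("consistency error: fingerprints have different lengths (",
         length(fpA), " vs ", length(fpB), ") and no position map given")
  keyOf <- function(e) paste(e$type, e$receptor_label, sep = "@")
  per <- list()
  for (p in seq_along(fpA@positions)) {
    q <- p
    if (!is.null(positionMap) && !is.na(positionMap[as.character(p)]))
      q <- positionMap[[as.character(p)]]
    ea <- fpA@positions[[p]]
    eb <- if (q >= 1 && q <= length(fpB)) fpB@positions[[q]] else
      data.frame(type = character(), receptor_label = character())
    ka <- keyOf(ea); kb <- keyOf(eb)
    per[[p]] <- list(gained = eb[!(kb %in% ka), , drop = FALSE],
                     lost = ea[!(ka %in% kb), , drop = FALSE],
                     conserved = ea[ka %in% kb, , drop = FALSE])
  }
  new("FingerprintDiff", perPosition = per, idA = fpA@complexId,
      idB = fpB@complexId)
}

#' Flatten a fingerprint diff to a data.frame
#'
#' @param x a [FingerprintDiff-class].
#' @param ... ignored.
#' @return data.frame with columns position, status
#'   (gained/lost/conserved), type, receptor_label.
#' @export
setMethod("as.data.frame", "FingerprintDiff", function(x, ...) {
  rows <- list()
  for (p in seq_along(x@perPosition)) {
    for (status in c("gained", "lost", "conserved")) {
      e <- x@perPosition[[p]][[status]]
      if (nrow(e))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(position = p, status = status), e)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(position = integer(), status = character(),
                      type = character(), receptor_label = character())
  rownames(out) <- NULL
  out
})

#' Summary counts of a fingerprint diff
#'
#' @param object a [FingerprintDiff-class].
#' @param ... ignored.
#' @return Named integer vector (gained, lost, conserved).
#' @export
setMethod("summary", "FingerprintDiff", function(object, ...) {
  counts <- vapply(c("gained", "lost", "conserved"), function(s)
    sum(vapply(object@perPosition, function(p) nrow(p[[s]]), 0L)), 0L)
  counts
})

setMethod("show", "FingerprintDiff", function(object) {
  s <- summary(object)
  cat("FingerprintDiff [", object@idA, " vs ", object@idB, "]: ",
      s["gained"], " gained, ", s["lost"], " lost, ", s["conserved"],
      " conserved\n", sep = "")
  invisible(object)
})
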