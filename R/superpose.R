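## superposition: Kabsch fit, C-alpha RMSD, displacement metrics, helix-axis
## rotation angle

.centroid <- function(m) colMeans(m)

#' Apply a rigid transform to coordinates
#'
#' @param xyz Nx3 coordinate matrix (Angstrom).
#' @param transform a [RigidTransform-class].
#' @return Transformed Nx3 matrix.
#' @export
applyTransform <- function(xyz, transform) {
  sweep(xyz %*% t(transform@rotation), 2, transform@translation, "+")
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation mapping `coordsB` onto
#' `coordsA` with minimal RMSD. Reflections are explicitly forbidden
#' via the determinant correction on the SVD solution, so the result
#' is always a proper rotation.
#'
#' @param coordsA,coordsB Nx3 matrices of paired coordinates
#'   (Angstrom), N >= 3 and not all collinear.
#' @param pairing optional data.frame recording the correspondence,
#'   carried into the result for audit.
#' @return A [SuperposeResult-class]; its transform maps B onto A.
#' @export
kabschFit <- function(coordsA, coordsB, pairing = data.frame()) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  n <- nrow(coordsA)
  if (n != nrow(coordsB)) stop("geometry error: point sets differ in size")
  if (n < 3L) stop("geometry error: need at least 3 paired points")
  ca <- .centroid(coordsA); cb <- .centroid(coordsB)
  A <- sweep(coordsA, 2, ca); B <- sweep(coordsB, 2, cb)
  # degenerate (collinear) point sets have rank < 2 cross-covariance
  if (sum(svd(A)$d > 1e-8) < 2L || sum(svd(B)$d > 1e-8) < 2L)
    stop("geometry error: degenerate (collinear) point set")
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  # row-vector convention: aligned = xyz %*% t(R) + trans
  trans <- as.numeric(ca - R %*% cb)
  aligned <- sweep(coordsB %*% t(R), 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((aligned - coordsA)^2)))
  new("SuperposeResult",
      transform = new("RigidTransform", rotation = R, translation = trans),
      rmsd = rmsd, nPairs = as.integer(n), pairing = pairing)
}

# pair atoms of two models by (chain, resno, insert, elety); byChain=FALSE
# pairs across renamed chains using (resno, insert, elety) only
.pairAtoms <- function(a, b, byChain = TRUE) {
  ka <- if (byChain) .atomKey(a) else paste(a$resno, a$insert, a$elety, sep = "|")
  kb <- if (byChain) .atomKey(b) else paste(b$resno, b$insert, b$elety, sep = "|")
  common <- intersect(ka, kb)
  list(a = a[match(common, ka), , drop = FALSE],
       b = b[match(common, kb), , drop = FALSE],
       keys = common)
}

#' C-alpha RMSD after optimal superposition
#'
#' Pairs residues by author residue number (the compared class B
#' structures share author numbering), requires the C-alpha present
#' in both, superposes on the paired set and reports the RMSD over
#' that same set. The pairing used is recorded for audit. An optional
#' region filter (e.g. `"TMD"`) restricts the atom set via attached
#' numbering, since published global RMSDs rarely state their atom
#' set.
#'
#' @param modelA,modelB [StructureModel-class] objects.
#' @param chainA,chainB receptor chain ids (default: all common
#'   chains, paired by chain id).
#' @param region optional region name(s) (requires [applyNumbering()]
#'   on both models); `"TMD"` expands to TM1..TM7.
#' @return A [SuperposeResult-class].
#' @export
caRmsd <- function(modelA, modelB, chainA = NULL, chainB = chainA,
                   region = NULL) {
  a <- modelA@atoms[modelA@atoms$elety == "CA", ]
  b <- modelB@atoms[modelB@atoms$elety == "CA", ]
  byChain <- is.null(chainA)
  if (!is.null(chainA)) a <- a[a$chain %in% chainA, ]
  if (!is.null(chainB)) b <- b[b$chain %in% chainB, ]
  if (!is.null(region)) {
    region <- unlist(lapply(region, function(v)
      if (!is.null(.REGION_ALIASES[[v]])) .REGION_ALIASES[[v]] else v))
    a <- a[!is.na(a$region) & a$region %in% region, ]
    b <- b[!is.na(b$region) & b$region %in% region, ]
  }
  p <- .pairAtoms(a, b, byChain = byChain)
  if (length(p$keys) < 3L)
    stop("geometry error: fewer than 3 paired C-alpha atoms")
  pairing <- data.frame(key = p$keys,
                        resid_a = p$a$resid, resid_b = p$b$resid,
                        stringsAsFactors = FALSE)
  kabschFit(as.matrix(p$a[, c("x", "y", "z")]),
            as.matrix(p$b[, c("x", "y", "z")]), pairing = pairing)
}

.parseAddress <- function(addr) {
  if (is.list(addr)) return(addr)
  parts <- strsplit(addr, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop("atom address must be 'chain:resno:atom', got '", addr, "'")
  list(chain = parts[1], resno = as.integer(parts[2]), elety = parts[3])
}

.getAtomXyz <- function(model, addr, what = "probe") {
  addr <- .parseAddress(addr)
  a <- model@atoms
  hit <- a$chain == addr$chain & a$resno == addr$resno & a$elety == addr$elety
  if (!any(hit))
    stop("addressing error: ", what, " atom ", addr$chain, ":", addr$resno,
         ":", addr$elety, " not found in ", model@sourceId)
  as.numeric(a[which(hit)[1], c("x", "y", "z")])
}

.frameFit <- function(modelA, modelB, frame) {
  fa <- selectAtoms(modelA, frame)@atoms
  fb <- selectAtoms(modelB, frame)@atoms
  p <- .pairAtoms(fa, fb)
  if (length(p$keys) < 3L)
    stop("geometry error: frame selection pairs fewer than 3 atoms")
  kabschFit(as.matrix(p$a[, c("x", "y", "z")]),
            as.matrix(p$b[, c("x", "y", "z")]),
            pairing = data.frame(key = p$keys, stringsAsFactors = FALSE))
}

#' Displacement of a named atom after framing on a reference selection
#'
#' Superposes model B onto model A over the frame selection, then
#' returns the Euclidean distance between the two placements of the
#' probe atom — the quantity behind statements like "shifted toward
#' the TMD core by 8.1 A (measured by the C-alpha of L27P)".
#'
#' @param modelA,modelB [StructureModel-class] objects.
#' @param frame selection expression pairing >= 3 atoms across both
#'   models (e.g. `"chain R and region TMD and name CA"`).
#' @param probe atom address `"chain:resno:atom"` (or list) present in
#'   both models.
#' @return Distance in Angstrom, with the frame fit attached as
#'   attribute `"fit"`.
#' @export
displacement <- function(modelA, modelB, frame, probe) {
  fit <- .frameFit(modelA, modelB, frame)
  pa <- .getAtomXyz(modelA, probe)
  pb <- applyTransform(rbind(.getAtomXyz(modelB, probe)), fit@transform)[1, ]
  structure(sqrt(sum((pa - pb)^2)), fit = fit)
}

#' Distance between two distinct atoms across framed models
#'
#' Like [displacement()], but the probes are structurally equivalent
#' yet non-identical residues in the two models (e.g. the ECL1
#' glycines G202 of GIPR vs G207 of GCGR).
#'
#' @inheritParams displacement
#' @param atomA address in `modelA`; `atomB` address in `modelB`.
#' @param atomB see `atomA`.
#' @return Distance in Angstrom with the frame fit attached.
#' @export
crossAtomDistance <- function(modelA, modelB, frame, atomA, atomB) {
  fit <- .frameFit(modelA, modelB, frame)
  pa <- .getAtomXyz(modelA, atomA, "atomA")
  pb <- applyTransform(rbind(.getAtomXyz(modelB, atomB, "atomB")),
                       fit@transform)[1, ]
  structure(sqrt(sum((pa - pb)^2)), fit = fit)
}

.principalAxis <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  svd(c0)$v[, 1]
}

#' Rotation angle between helix axes after framing
#'
#' After superposing on the frame, fits the dominant principal
#' component of each helix C-alpha cloud (parameter-free and stable
#' for helices of two or more turns) and returns the acute angle
#' between the two axes, in degrees. Only magnitudes are reported:
#' sign and handedness are not.
#'
#' @inheritParams displacement
#' @param helix selection expression giving >= 6 consecutive C-alpha
#'   atoms in both models (e.g. `"chain P and name CA"`).
#' @return Angle in degrees within `[0, 90]`.
#' @export
axisRotationAngle <- function(modelA, modelB, frame, helix) {
  fit <- .frameFit(modelA, modelB, frame)
  ha <- selectAtoms(modelA, helix)@atoms
  hb <- selectAtoms(modelB, helix)@atoms
  ha <- ha[ha$elety == "CA", ]; hb <- hb[hb$elety == "CA", ]
  if (nrow(ha) < 6L || nrow(hb) < 6L)
    stop("geometry error: helix selection needs >= 6 C-alpha atoms")
  axA <- .principalAxis(as.matrix(ha[, c("x", "y", "z")]))
  axB <- .principalAxis(applyTransform(as.matrix(hb[, c("x", "y", "z")]),
                                       fit@transform))
  ang <- acos(pmin(1, abs(sum(axA * axB)))) * 180 / pi
  structure(ang, fit = fit)
}

#' @describeIn SuperposeResult-class RMSD accessor
#' @param object a SuperposeResult
#' @export
setGeneric("rmsd", function(object) standardGeneric("rmsd"))

#' @rdname SuperposeResult-class
#' @export
setMethod("rmsd", "SuperposeResult", function(object) object@rmsd)

setMethod("show", "SuperposeResult", function(object) {
  cat("SuperposeResult: RMSD", format(object@rmsd, digits = 4), "A over",
      object@nPairs, "paired atoms\n")
  invisible(object)
})
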