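## surface: Shrake-Rupley SASA and delta-SASA buried/interface areas

#' Default van der Waals radii (Bondi-type)
#'
#' C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20, halogens per Bondi;
#' unknown elements fall back to `default` (1.80 A) with a warning at
#' computation time. All values in Angstrom.
#'
#' @param default radius used for unlisted elements.
#' @return Named numeric vector of radii with attribute `default`.
#' @export
defaultRadii <- function(default = 1.80) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
         F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
  structure(r, default = default)
}

# deterministic golden-spiral lattice on the unit sphere (no RNG)
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.atomRadii <- function(elements, radii) {
  r <- radii[elements]
  unknown <- is.na(r)
  if (any(unknown)) {
    def <- attr(radii, "default")
    if (is.null(def))
      stop("radii error: unknown element(s) ",
           paste(unique(elements[unknown]), collapse = ", "),
           " and no default radius")
    warning("unknown element(s) ", paste(unique(elements[unknown]),
            collapse = ", "), "; using default radius ", def, " A")
    r[unknown] <- def
  }
  unname(r)
}

.sasaXyz <- function(xyz, radii_per_atom, probe, nPoints) {
  n <- nrow(xyz)
  pts <- .spherePoints(nPoints)
  rp <- radii_per_atom + probe
  per <- numeric(n)
  if (n == 1L) return(4 * pi * rp^2)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    # neighbours whose probe-inflated spheres can occlude atom i
    nb <- which(d2[i, ] < (rp[i] + rp)^2 & seq_len(n) != i)
    sp <- sweep(pts * rp[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, nPoints)
      for (j in nb) {
        dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        acc <- acc & dj2 > rp[j]^2
        if (!any(acc)) break
      }
      frac <- sum(acc) / nPoints
    } else frac <- 1
    per[i] <- 4 * pi * rp[i]^2 * frac
  }
  per
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by test points on a deterministic golden-spiral
#' lattice (no random number generation, so results are exactly
#' reproducible). Hydrogens are excluded by default since cryo-EM
#' models are heavy-atom only.
#'
#' @param model a non-empty [StructureModel-class].
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param nPoints quadrature points per atom sphere (>= 64).
#' @param radii named radii vector, see [defaultRadii()].
#' @param includeH include hydrogen atoms.
#' @return An [AreaResult-class].
#' @export
sasa <- function(model, probe = 1.4, nPoints = 1920L, radii = defaultRadii(),
                 includeH = FALSE) {
  stopifnot(is(model, "StructureModel"), probe > 0, nPoints >= 64L)
  a <- model@atoms
  if (!includeH) a <- a[a$element != "H", , drop = FALSE]
  if (nrow(a) == 0L) stop("empty model: no atoms to compute SASA for")
  per <- .sasaXyz(as.matrix(a[, c("x", "y", "z")]),
                  .atomRadii(a$element, radii), probe, as.integer(nPoints))
  names(per) <- paste(a$chain, a$resno, a$elety, sep = ":")
  new("AreaResult", perAtom = per, total = sum(per), probeRadius = probe,
      nPoints = as.integer(nPoints))
}

.resolveSelection <- function(model, sel) {
  if (is(sel, "StructureModel")) sel else selectAtoms(model, sel)
}

#' Buried surface area between two selections (delta-SASA)
#'
#' Returns `SASA(A alone) + SASA(B alone) - SASA(A and B together)`.
#' Under the default `context = "stripped"` the two selections are
#' the only atoms present (the rest of the structure is absent);
#' `context = "complex"` computes each side's reference SASA in the
#' context of the full model minus the partner selection, and the
#' bound-state SASA in the full model. Both conventions are reported
#' side by side by [runComparison()].
#'
#' @param model a [StructureModel-class].
#' @param selA,selB disjoint selection expressions or sub-models.
#' @param probe probe radius, Angstrom.
#' @param nPoints quadrature points per atom sphere.
#' @param context `"stripped"` or `"complex"` (see Details).
#' @return Buried area in Angstrom^2 (non-negative up to quadrature
#'   noise).
#' @export
buriedSurfaceArea <- function(model, selA, selB, probe = 1.4, nPoints = 1920L,
                              context = c("stripped", "complex")) {
  context <- match.arg(context)
  ma <- .resolveSelection(model, selA)
  mb <- .resolveSelection(model, selB)
  ka <- .atomKey(ma@atoms); kb <- .atomKey(mb@atoms)
  if (length(intersect(ka, kb)))
    stop("selection error: selections overlap (",
         paste(utils::head(intersect(ka, kb), 3), collapse = ", "), " ...)")
  sumSel <- function(res, keys) sum(res@perAtom[names(res@perAtom) %in% keys])
  keyOf <- function(m) paste(m@atoms$chain, m@atoms$resno, m@atoms$elety,
                             sep = ":")
  if (context == "stripped") {
    ab <- ma; ab@atoms <- rbind(ma@atoms, mb@atoms)
    tA <- sasa(ma, probe, nPoints)@total
    tB <- sasa(mb, probe, nPoints)@total
    tAB <- sasa(ab, probe, nPoints)@total
    tA + tB - tAB
  } else {
    full <- model
    notB <- model; notB@atoms <- model@atoms[!(.atomKey(model@atoms) %in% kb), ]
    notA <- model; notA@atoms <- model@atoms[!(.atomKey(model@atoms) %in% ka), ]
    sFull <- sasa(full, probe, nPoints)
    sNotB <- sasa(notB, probe, nPoints)
    sNotA <- sasa(notA, probe, nPoints)
    (sumSel(sNotB, keyOf(ma)) - sumSel(sFull, keyOf(ma))) +
      (sumSel(sNotA, keyOf(mb)) - sumSel(sFull, keyOf(mb)))
  }
}

#' Interface area between two selections
#'
#' One-sided interface area, i.e. [buriedSurfaceArea()] divided by two
#' (the average of the two components' buried areas) under the
#' default convention; `oneSided = FALSE` returns the full delta-SASA.
#' Published interface areas use either convention, so
#' [runComparison()] always reports both.
#'
#' @inheritParams buriedSurfaceArea
#' @param oneSided divide the delta-SASA by two (default TRUE).
#' @return Interface area in Angstrom^2.
#' @export
interfaceArea <- function(model, selA, selB, probe = 1.4, nPoints = 1920L,
                          context = c("stripped", "complex"),
                          oneSided = TRUE) {
  bsa <- buriedSurfaceArea(model, selA, selB, probe, nPoints, context)
  if (oneSided) bsa / 2 else bsa
}

setMethod("show", "AreaResult", function(object) {
  cat("AreaResult: total", format(object@total, digits = 6), "A^2 over",
      length(object@perAtom), "atoms (probe ", object@probeRadius,
      " A, ", object@nPoints, " points)\n", sep = "")
  invisible(object)
})
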