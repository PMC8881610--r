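## pharmacology: three-parameter logistic concentration-response fitting,
## pEC50/fold-shift, WT-normalisation, BRET baseline-corrected AUC

.logistic3 <- function(conc, bottom, top, pec50) {
  bottom + (top - bottom) / (1 + 10^(-(pec50 + log10(conc))))
}

.logistic3h <- function(conc, bottom, top, pec50, hillSlope = 1) {
  bottom + (top - bottom) / (1 + 10^(-hillSlope * (pec50 + log10(conc))))
}

.checkCurve <- function(conc, resp) {
  if (length(conc) != length(resp)) stop("concentration/response length mismatch")
  if (any(conc <= 0)) stop("concentrations must be positive (molar)")
  u <- sort(unique(conc))
  if (length(u) < 4L)
    stop("dose-response curve needs >= 4 distinct concentrations")
  if (log10(max(u) / min(u)) < 2)
    stop("dose-response curve must span >= 2 log units")
  invisible(TRUE)
}

#' Fit a three-parameter logistic concentration-response curve
#'
#' Model: `response = bottom + (top - bottom) / (1 + EC50/conc)` —
#' equivalently `bottom + (top - bottom) / (1 + 10^(-(pEC50 +
#' log10(conc))))` — with Hill slope fixed at 1, i.e. three free
#' parameters (bottom, top, pEC50), the standard "three-parameter
#' logistic equation" of dose-response analysis. Replicates are
#' fitted as pooled points. Initialisation is deterministic: bottom =
#' min response, top = max response, pEC50 = -log10 of the dose whose
#' mean response is nearest half-maximal, so identical data give
#' identical fits. Standard errors come from the least-squares
#' curvature. Degenerate (flat, non-converging) data yield
#' `converged = FALSE` rather than silent numbers; an EC50 more than
#' two orders of magnitude outside the tested range is flagged
#' `extrapolated`.
#'
#' @param data data.frame with columns `concentration_M` and
#'   `response` (optionally `replicate`, `experiment`), or a numeric
#'   vector of concentrations when `response` is supplied.
#' @param response numeric responses when `data` is a concentration
#'   vector.
#' @param hillSlope fix the Hill slope at a value other than 1 to get
#'   the four-parameter variant's fixed-slope analogue (the slope is
#'   never fitted here).
#' @return A [LogisticFit-class].
#' @export
fitLogistic3 <- function(data, response = NULL, hillSlope = 1) {
  if (is.data.frame(data)) {
    conc <- data$concentration_M; resp <- data$response
  } else {
    conc <- data; resp <- response
  }
  .checkCurve(conc, resp)
  means <- tapply(resp, conc, mean)
  doses <- as.numeric(names(means))
  half <- (min(means) + max(means)) / 2
  start <- list(bottom = min(resp), top = max(resp),
                pec50 = -log10(doses[which.min(abs(means - half))]))
  residFun <- function(par)
    .logistic3h(conc, par[1], par[2], par[3], hillSlope) - resp
  out <- tryCatch(
    minpack.lm::nls.lm(par = unlist(start), fn = residFun,
                       control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           maxfev = 2000)),
    error = function(e) NULL)
  if (is.null(out) || !out$info %in% 1:4 || !all(is.finite(out$par))) {
    return(new("LogisticFit", bottom = start$bottom, top = start$top,
               pec50 = NA_real_,
               se = c(bottom = NA_real_, top = NA_real_, pec50 = NA_real_),
               converged = FALSE, extrapolated = FALSE,
               nObs = length(resp)))
  }
  est <- out$par
  names(est) <- c("bottom", "top", "pec50")
  # standard errors from the least-squares curvature (J'J at the optimum)
  dof <- length(resp) - 3L
  sigma2 <- if (dof > 0) out$deviance / dof else 0
  se <- tryCatch(sqrt(diag(sigma2 * solve(out$hessian))),
                 error = function(e) rep(NA_real_, 3))
  names(se) <- names(est)
  span <- est["top"] - est["bottom"]
  # a usable fit needs top > bottom with the span resolved above the
  # residual noise
  converged <- is.finite(est["pec50"]) && span > 0 &&
    span > 2 * sqrt(sigma2) / sqrt(length(resp))
  ec50 <- 10^(-est[["pec50"]])
  extrapolated <- ec50 < min(conc) * 1e-2 || ec50 > max(conc) * 1e2
  new("LogisticFit", bottom = unname(est["bottom"]), top = unname(est["top"]),
      pec50 = unname(est["pec50"]),
      se = c(bottom = unname(se["bottom"]), top = unname(se["top"]),
             pec50 = unname(se["pec50"])),
      converged = unname(converged), extrapolated = extrapolated,
      nObs = length(resp))
}

#' Fit per independent experiment and aggregate
#'
#' Published potencies are typically "means +/- S.E.M. of n
#' independent experiments": each experiment is fitted separately and
#' the pEC50s averaged. Pooled fitting remains available through
#' [fitLogistic3()] directly.
#'
#' @param data data.frame with columns `concentration_M`, `response`,
#'   `experiment`.
#' @return list with `fits` (per experiment), `pec50_mean`,
#'   `pec50_sem`, `n`.
#' @export
fitByExperiment <- function(data) {
  stopifnot("experiment" %in% names(data))
  fits <- lapply(split(data, data$experiment), fitLogistic3)
  p <- vapply(fits, function(f) if (f@converged) f@pec50 else NA_real_, 0)
  p <- p[is.finite(p)]
  list(fits = fits, pec50_mean = mean(p),
       pec50_sem = stats::sd(p) / sqrt(length(p)), n = length(p))
}

#' pEC50 accessor
#'
#' @param fit a converged [LogisticFit-class].
#' @return pEC50 (-log10 EC50 in molar).
#' @export
pec50 <- function(fit) {
  if (!fit@converged) stop("propagation error: fit did not converge")
  fit@pec50
}

#' Potency fold-shift between two fits
#'
#' `10^(pEC50_ref - pEC50_test)`; values above 1 mean the test curve
#' is less potent (right-shifted), e.g. a binding-site mutant versus
#' wild type.
#'
#' @param fitTest,fitRef converged [LogisticFit-class] objects.
#' @return Fold shift (dimensionless).
#' @export
foldShift <- function(fitTest, fitRef) {
  10^(pec50(fitRef) - pec50(fitTest))
}

#' Normalize responses to a reference (percent of reference)
#'
#' @param values numeric vector.
#' @param reference positive scalar (e.g. the wild-type response).
#' @return `values / reference * 100`.
#' @export
normalizeToReference <- function(values, reference) {
  if (!is.numeric(reference) || length(reference) != 1L || !is.finite(reference)
      || reference <= 0)
    stop("normalization error: reference must be a positive scalar")
  values / reference * 100
}

#' Construct a BRET kinetic series
#'
#' @param ratios matrix of 535/470 nm emission ratios, one row per
#'   measurement cycle, one column per condition; column names label
#'   the conditions and must include the vehicle trace.
#' @param nBaselineCycles number of cycles recorded before ligand
#'   addition (they precede the stimulus cycles).
#' @param cycleDuration seconds per cycle.
#' @param vehicle column name of the vehicle-treated trace.
#' @return list of class `BretTimeSeries`.
#' @export
bretTimeSeries <- function(ratios, nBaselineCycles, cycleDuration,
                           vehicle = "vehicle") {
  ratios <- as.matrix(ratios)
  stopifnot(nBaselineCycles >= 1, nBaselineCycles < nrow(ratios),
            cycleDuration > 0)
  if (any(ratios <= 0)) stop("BRET ratios must be positive")
  structure(list(ratios = ratios, nBaselineCycles = as.integer(nBaselineCycles),
                 cycleDuration = cycleDuration, vehicle = vehicle),
            class = "BretTimeSeries")
}

#' Baseline- and vehicle-corrected BRET area under the curve
#'
#' Each trace is corrected to its own pre-stimulus baseline mean, then
#' to the vehicle-treated trace; the ligand-induced response is
#' integrated by the trapezoid rule over the measured stimulus cycles.
#' Units: delta-ratio x seconds. The integration spans the stimulus
#' samples, i.e. `(n_stimulus_cycles - 1) * cycleDuration`.
#'
#' @param series a [bretTimeSeries()].
#' @return Named numeric vector of AUC values, one per non-vehicle
#'   condition.
#' @export
bretAuc <- function(series) {
  stopifnot(inherits(series, "BretTimeSeries"))
  r <- series$ratios
  if (!series$vehicle %in% colnames(r))
    stop("correction error: vehicle trace '", series$vehicle, "' missing")
  nb <- series$nBaselineCycles
  base <- colMeans(r[seq_len(nb), , drop = FALSE])
  delta <- sweep(r, 2, base)                       # corrected to baseline
  corrected <- delta - delta[, series$vehicle]     # then to vehicle
  stim <- corrected[(nb + 1):nrow(r), , drop = FALSE]
  tt <- (seq_len(nrow(stim)) - 1) * series$cycleDuration
  auc <- apply(stim, 2, function(y)
    sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
  auc[setdiff(colnames(r), series$vehicle)]
}

#' Two-tailed t-test on sets of pEC50 values
#'
#' Convenience wrapper for comparing potencies across independent
#' experiments, as in "statistically significant differences were
#' determined with a two-tailed Student's t test".
#'
#' @param pec50A,pec50B numeric vectors of per-experiment pEC50s.
#' @param ... passed to [stats::t.test()].
#' @return An `htest` object.
#' @export
pec50Ttest <- function(pec50A, pec50B, ...) {
  stats::t.test(pec50A, pec50B, alternative = "two.sided", ...)
}

setMethod("show", "LogisticFit", function(object) {
  if (object@converged) {
    cat(sprintf(
      "LogisticFit: bottom %.3g, top %.3g, pEC50 %.3f (EC50 %.3g M), n = %d%s\n",
      object@bottom, object@top, object@pec50, 10^(-object@pec50),
      object@nObs, if (object@extrapolated) " [extrapolated]" else ""))
  } else {
    cat("LogisticFit: NOT converged (flat or degenerate data), n =",
        object@nObs, "\n")
  }
  invisible(object)
})
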