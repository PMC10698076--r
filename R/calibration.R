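# Threshold calibration between deconvolution engines.
#
# The calibration maps a reference engine's lesion threshold to the
# equivalent threshold of another engine via the linear regressions of
# engine-estimated parameters against phantom ground truth. Relative CBF is
# defined against the engine's own estimate for normally perfused tissue
# (ground-truth CBF N_GT), read off the engine's regression line.

#' Per-combination mean estimates
#'
#' Averages engine estimates over the noise realizations of each phantom
#' parameter combination, the quantity entered into the calibration
#' regressions.
#'
#' @param results A data.frame from [deconvolve_phantom()].
#' @param phantom The `phantom_dataset` the results came from (checked for
#'   completeness).
#' @return A data.frame with one row per combination: ground truth columns
#'   (`gt_*`) and mean `CBF`, `CBV`, `MTT`, `Tmax`.
#' @export
summarize_estimates <- function(results, phantom = NULL) {
  needed <- c("combo", "gt_T0", "gt_MTT", "gt_CBV", "gt_CBF", "gt_Tmax",
              "CBF", "CBV", "MTT", "Tmax")
  if (!all(needed %in% names(results))) {
    stop("summarize_estimates: results lack required columns", call. = FALSE)
  }
  if (!is.null(phantom)) {
    missing <- setdiff(seq_len(nrow(phantom$combos)), unique(results$combo))
    if (length(missing)) {
      stop(sprintf("summarize_estimates: no estimates for %d combos (first: %d)",
                   length(missing), missing[1]), call. = FALSE)
    }
  }
  agg <- stats::aggregate(
    results[, c("CBF", "CBV", "MTT", "Tmax")],
    by = list(combo = results$combo), FUN = mean
  )
  gt <- unique(results[, c("combo", "gt_T0", "gt_MTT", "gt_CBV", "gt_CBF", "gt_Tmax")])
  out <- merge(gt, agg, by = "combo", sort = TRUE)
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares regression of estimates on ground truth
#'
#' Fits estimate = slope * truth + intercept with a free intercept (no
#' zero-intercept constraint: the non-negativity of perfusion estimates
#' biases low-SNR fits upward, which the intercept absorbs).
#'
#' @param gt_values Ground-truth values (regressor).
#' @param est_values Estimated values (response), same length.
#' @param exclude Optional logical vector: combinations to drop before
#'   fitting (e.g. the low-SNR CBV = 0.5 ml/100 g points for Tmax fits).
#' @return A `regression_fit` list: `slope`, `intercept`, `r2`, `n`.
#' @export
fit_regression <- function(gt_values, est_values, exclude = NULL) {
  stopifnot(length(gt_values) == length(est_values))
  keep <- rep(TRUE, length(gt_values))
  if (!is.null(exclude)) keep <- keep & !exclude
  x <- gt_values[keep]
  y <- est_values[keep]
  if (length(x) < 2L) stop("fit_regression: fewer than 2 points after exclusion", call. = FALSE)
  if (stats::var(x) == 0) stop("fit_regression: ground truth has zero variance", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    n = length(x)
  ), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> est = %.4f * truth + %.4f  (R2 %.3f, n %d)\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Calibrate the relative-CBF (ischemic core) threshold
#'
#' Closed-form mapping of a reference relative-CBF threshold `R_MI` between
#' two engines from their CBF regressions against ground truth (slopes
#' alpha, intercepts beta):
#' \deqn{R_{MB} = \frac{\alpha_{MB}(\alpha_{MI} N_{GT} + \beta_{MI}) R_{MI}
#'   + \alpha_{MI}\beta_{MB} - \alpha_{MB}\beta_{MI}}
#'   {\alpha_{MI}(\alpha_{MB} N_{GT} + \beta_{MB})}.}
#' `N_GT` is the assumed ground-truth CBF of normally perfused brain used to
#' convert absolute to relative CBF (each engine's reference CBF is its own
#' regression prediction at N_GT). The result is also rounded to the nearest
#' 5 percentage points (halfway rounds up), the granularity at which core
#' thresholds are used clinically.
#'
#' @param fit_mi Reference-engine CBF [fit_regression()] fit.
#' @param fit_mb Target-engine CBF fit.
#' @param R_MI Reference relative-CBF threshold, fraction (default 0.30).
#' @param N_GT Normal-brain ground-truth CBF, ml/min/100 g (default 50).
#' @return A `cbf_calibration` list: `r_mb` (fraction), `r_mb_rounded`
#'   (fraction, nearest 0.05), plus echoed inputs.
#' @export
calibrate_cbf_threshold <- function(fit_mi, fit_mb, R_MI = 0.30, N_GT = 50) {
  a_mi <- fit_mi$slope; b_mi <- fit_mi$intercept
  a_mb <- fit_mb$slope; b_mb <- fit_mb$intercept
  if (a_mi <= 0 || a_mb <= 0) {
    stop("calibrate_cbf_threshold: regression slopes must be positive", call. = FALSE)
  }
  den <- a_mi * (a_mb * N_GT + b_mb)
  if (abs(den) < .Machine$double.eps) {
    stop("calibrate_cbf_threshold: degenerate calibration (zero denominator)", call. = FALSE)
  }
  num <- a_mb * (a_mi * N_GT + b_mi) * R_MI + a_mi * b_mb - a_mb * b_mi
  r_mb <- num / den
  if (r_mb <= 0) {
    stop("calibrate_cbf_threshold: calibrated threshold is non-positive", call. = FALSE)
  }
  structure(list(
    r_mb = r_mb,
    r_mb_rounded = round_to_step(r_mb, 0.05),
    R_MI = R_MI, N_GT = N_GT, fit_mi = fit_mi, fit_mb = fit_mb
  ), class = "cbf_calibration")
}

#' @export
print.cbf_calibration <- function(x, ...) {
  cat(sprintf("<cbf_calibration> relative CBF threshold %.1f%% (rounded %.0f%%), reference %.0f%%\n",
              100 * x$r_mb, 100 * x$r_mb_rounded, 100 * x$R_MI))
  invisible(x)
}

#' Calibrate the Tmax (penumbra) threshold
#'
#' Closed-form mapping of a reference Tmax threshold between two engines from
#' their Tmax regressions against ground truth (slopes gamma, intercepts
#' delta):
#' \deqn{T_{max,MB} = \frac{\gamma_{MB}}{\gamma_{MI}} T_{max,MI}
#'   + \frac{\gamma_{MI}\delta_{MB} - \gamma_{MB}\delta_{MI}}{\gamma_{MI}}.}
#' The result is also rounded to the nearest integer second (halfway up).
#'
#' @param fit_mi Reference-engine Tmax [fit_regression()] fit.
#' @param fit_mb Target-engine Tmax fit.
#' @param T_MI Reference Tmax threshold, s (default 6).
#' @return A `tmax_calibration` list: `tmax_mb` (s), `tmax_rounded` (s),
#'   plus echoed inputs.
#' @export
calibrate_tmax_threshold <- function(fit_mi, fit_mb, T_MI = 6.0) {
  g_mi <- fit_mi$slope; d_mi <- fit_mi$intercept
  g_mb <- fit_mb$slope; d_mb <- fit_mb$intercept
  if (g_mi == 0) stop("calibrate_tmax_threshold: zero reference slope", call. = FALSE)
  tmax_mb <- (g_mb / g_mi) * T_MI + (g_mi * d_mb - g_mb * d_mi) / g_mi
  if (tmax_mb <= 0) {
    stop("calibrate_tmax_threshold: calibrated threshold is non-positive", call. = FALSE)
  }
  structure(list(
    tmax_mb = tmax_mb,
    tmax_rounded = round_to_step(tmax_mb, 1),
    T_MI = T_MI, fit_mi = fit_mi, fit_mb = fit_mb
  ), class = "tmax_calibration")
}

#' @export
print.tmax_calibration <- function(x, ...) {
  cat(sprintf("<tmax_calibration> Tmax threshold %.2f s (rounded %.0f s), reference %.0f s\n",
              x$tmax_mb, x$tmax_rounded, x$T_MI))
  invisible(x)
}

#' Full phantom calibration workflow
#'
#' Runs the reference (model-independent) engine and a target engine over a
#' phantom, regresses per-combination mean CBF and Tmax against ground truth
#' (Tmax fits exclude the low-SNR CBV = 0.5 ml/100 g combinations for all
#' engines), and evaluates both closed-form threshold calibrations.
#'
#' @param phantom A `phantom_dataset`.
#' @param target Target engine, `"md"` or `"jwl"`.
#' @param R_MI,N_GT,T_MI Calibration constants; see
#'   [calibrate_cbf_threshold()] and [calibrate_tmax_threshold()].
#' @param cbv_exclude CBV value (ml/100 g) excluded from Tmax regressions.
#' @param reg_frac Regularization fraction of the reference engine.
#' @return A `calibration_report` list: per-engine fits, both calibration
#'   objects, and the per-combination summary tables.
#' @export
calibrate_phantom <- function(phantom, target = c("md", "jwl"),
                              R_MI = 0.30, N_GT = 50, T_MI = 6.0,
                              cbv_exclude = 0.5, reg_frac = 0.2) {
  target <- match.arg(target)
  res_mi <- deconvolve_phantom(phantom, "mi", reg_frac = reg_frac)
  res_mb <- deconvolve_phantom(phantom, target)
  sum_mi <- summarize_estimates(res_mi, phantom)
  sum_mb <- summarize_estimates(res_mb, phantom)
  excl <- sum_mi$gt_CBV == cbv_exclude
  fits <- list(
    cbf_mi = fit_regression(sum_mi$gt_CBF, sum_mi$CBF),
    cbf_mb = fit_regression(sum_mb$gt_CBF, sum_mb$CBF),
    tmax_mi = fit_regression(sum_mi$gt_Tmax, sum_mi$Tmax, exclude = excl),
    tmax_mb = fit_regression(sum_mb$gt_Tmax, sum_mb$Tmax, exclude = excl)
  )
  structure(list(
    target = target,
    fits = fits,
    cbf = calibrate_cbf_threshold(fits$cbf_mi, fits$cbf_mb, R_MI, N_GT),
    tmax = calibrate_tmax_threshold(fits$tmax_mi, fits$tmax_mb, T_MI),
    summary_mi = sum_mi, summary_mb = sum_mb
  ), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> reference mi vs target %s\n", x$target))
  cat(sprintf("  CBF fits:  mi slope %.3f int %.3f | %s slope %.3f int %.3f\n",
              x$fits$cbf_mi$slope, x$fits$cbf_mi$intercept, x$target,
              x$fits$cbf_mb$slope, x$fits$cbf_mb$intercept))
  cat(sprintf("  Tmax fits: mi slope %.3f int %.3f | %s slope %.3f int %.3f\n",
              x$fits$tmax_mi$slope, x$fits$tmax_mi$intercept, x$target,
              x$fits$tmax_mb$slope, x$fits$tmax_mb$intercept))
  cat(sprintf("  calibrated: relative CBF %.1f%% -> %.0f%%, Tmax %.2f s -> %.0f s\n",
              100 * x$cbf$r_mb, 100 * x$cbf$r_mb_rounded,
              x$tmax$tmax_mb, x$tmax$tmax_rounded))
  invisible(x)
}
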