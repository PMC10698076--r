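# Agreement statistics used to compare lesion measurements between engines.

#' Bland-Altman analysis
#'
#' Mean difference and 95\% limits of agreement between paired measurements.
#' Differences follow the convention reference minus compared, so a positive
#' mean difference means the compared technique underestimates the reference.
#'
#' @param ref Reference values. @param cmp Compared values, same length.
#' @return A `bland_altman` list: `mean_diff`, `loa_low`, `loa_high`
#'   (mean +/- 1.96 sample SD), `sd_diff`, `n`.
#' @export
bland_altman <- function(ref, cmp) {
  if (length(ref) != length(cmp)) stop("bland_altman: length mismatch", call. = FALSE)
  if (length(ref) < 2L) stop("bland_altman: need at least 2 pairs", call. = FALSE)
  d <- ref - cmp
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 sd_diff = s, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> mean diff %+.2f (95%% LoA %.2f to %.2f), n = %d\n",
              x$mean_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

# Categorical interpretation bands for kappa.
kappa_category <- function(k) {
  if (k < 0) "no agreement"
  else if (k <= 0.20) "slight"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "excellent"
}

#' Cohen's kappa for binary ratings
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e) with an
#' asymptotic 95\% confidence interval (SE = sqrt(p_o (1 - p_o) / n) /
#' (1 - p_e)), and the categorical interpretation: no agreement (< 0),
#' slight (0-0.20), fair (0.21-0.40), moderate (0.41-0.60), substantial
#' (0.61-0.80), excellent (0.81-1.00). When chance agreement is exactly 1
#' (both raters constant) and observed agreement is perfect, kappa is 1 by
#' convention and flagged.
#'
#' @param labels_a,labels_b Equal-length binary label vectors (logical, or
#'   any 2-level vectors coded consistently).
#' @return A `kappa_result` list: `kappa`, `ci_low`, `ci_high`, `category`,
#'   `p_o`, `p_e`, `n`, `degenerate`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("cohens_kappa: length mismatch", call. = FALSE)
  n <- length(labels_a)
  if (n < 2L) stop("cohens_kappa: need at least 2 ratings", call. = FALSE)
  a <- as.integer(as.factor(labels_a))
  b <- as.integer(as.factor(labels_b))
  lev <- union(unique(a), unique(b))
  if (length(lev) > 2L) stop("cohens_kappa: labels must be binary", call. = FALSE)
  p_o <- mean(a == b)
  p_e <- sum(vapply(lev, function(l) mean(a == l) * mean(b == l), numeric(1)))
  degenerate <- FALSE
  if (1 - p_e < .Machine$double.eps) {
    degenerate <- TRUE
    k <- if (p_o == 1) 1 else 0
    se <- 0
  } else {
    k <- (p_o - p_e) / (1 - p_e)
    se <- sqrt(p_o * (1 - p_o) / n) / (1 - p_e)
  }
  structure(list(
    kappa = k,
    ci_low = max(-1, k - 1.96 * se), ci_high = min(1, k + 1.96 * se),
    category = kappa_category(k),
    p_o = p_o, p_e = p_e, n = n, degenerate = degenerate
  ), class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa %.2f (95%% CI %.2f-%.2f), %s agreement%s\n",
              x$kappa, x$ci_low, x$ci_high, x$category,
              if (x$degenerate) " [degenerate table]" else ""))
  invisible(x)
}

#' Sensitivity, specificity and accuracy
#'
#' Standard 2x2 classification metrics of a predicted binary label against a
#' reference, reported both as fractions and as "k/n" counts. Undefined
#' metrics (no positives or no negatives in the reference) are returned as
#' `NA` with a flag rather than silently zeroed.
#'
#' @param reference Reference binary labels (logical; TRUE = positive).
#' @param predicted Predicted binary labels, same length.
#' @return A `classification_metrics` list: `sensitivity`, `specificity`,
#'   `accuracy` (fractions), `counts` (TP/FP/TN/FN), `display` ("k/n"
#'   strings), `undefined` (character vector of undefined metrics).
#' @export
classification_metrics <- function(reference, predicted) {
  if (length(reference) != length(predicted)) {
    stop("classification_metrics: length mismatch", call. = FALSE)
  }
  ref <- as.logical(reference)
  prd <- as.logical(predicted)
  tp <- sum(ref & prd); fn <- sum(ref & !prd)
  tn <- sum(!ref & !prd); fp <- sum(!ref & prd)
  n_pos <- tp + fn; n_neg <- tn + fp
  undefined <- character(0)
  sens <- if (n_pos > 0) tp / n_pos else { undefined <- c(undefined, "sensitivity"); NA_real_ }
  spec <- if (n_neg > 0) tn / n_neg else { undefined <- c(undefined, "specificity"); NA_real_ }
  acc <- (tp + tn) / length(ref)
  structure(list(
    sensitivity = sens, specificity = spec, accuracy = acc,
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    display = c(
      sensitivity = sprintf("%d/%d", tp, n_pos),
      specificity = sprintf("%d/%d", tn, n_neg),
      accuracy = sprintf("%d/%d", tp + tn, length(ref))
    ),
    undefined = undefined
  ), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  fmt <- function(v, s) if (is.na(v)) sprintf("%s (undefined)", s) else sprintf("%s (%.0f%%)", s, 100 * v)
  cat(sprintf("<classification_metrics> sensitivity %s  specificity %s  accuracy %s\n",
              fmt(x$sensitivity, x$display["sensitivity"]),
              fmt(x$specificity, x$display["specificity"]),
              fmt(x$accuracy, x$display["accuracy"])))
  invisible(x)
}

#' Pearson correlation
#'
#' Product-moment correlation with basic degeneracy guards.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_r: length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("pearson_r: need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("pearson_r: zero variance input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Agreement report between two lesion-report collections
#'
#' Builds a Table-2-style comparison of two engines' lesion reports:
#' favourable/unfavourable agreement overall and per criterion, with
#' sensitivity/specificity/accuracy (reference = first collection) and
#' Cohen's kappa.
#'
#' @param ref_reports,cmp_reports Lists of `lesion_report` objects (same
#'   patients, same order).
#' @return A data.frame with one row per criterion.
#' @export
agreement_report <- function(ref_reports, cmp_reports) {
  stopifnot(length(ref_reports) == length(cmp_reports))
  pull <- function(reports, fn) vapply(reports, fn, logical(1))
  rows <- list(
    target_mismatch = function(r) r$favourable,
    core_lt_70 = function(r) r$criteria$core_lt_70,
    penumbra_ge_15 = function(r) r$criteria$penumbra_ge_15,
    ratio_ge_1.8 = function(r) r$criteria$ratio_ge_1.8
  )
  out <- lapply(names(rows), function(nm) {
    ref <- pull(ref_reports, rows[[nm]])
    cmp <- pull(cmp_reports, rows[[nm]])
    cm <- classification_metrics(ref, cmp)
    kp <- tryCatch(cohens_kappa(ref, cmp), error = function(e) NULL)
    data.frame(
      criterion = nm,
      sensitivity = cm$sensitivity, specificity = cm$specificity,
      accuracy = cm$accuracy,
      kappa = if (is.null(kp)) NA_real_ else kp$kappa,
      kappa_ci_low = if (is.null(kp)) NA_real_ else kp$ci_low,
      kappa_ci_high = if (is.null(kp)) NA_real_ else kp$ci_high,
      category = if (is.null(kp)) NA_character_ else kp$category
    )
  })
  do.call(rbind, out)
}
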