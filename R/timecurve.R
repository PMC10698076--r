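#' Time-density curve
#'
#' A sampled contrast-concentration curve: times in seconds and values in
#' baseline-subtracted Hounsfield units (HU). The basic container passed
#' between the phantom simulator and the deconvolution engines.
#'
#' @param t Numeric vector of sample times (s), strictly increasing, length
#'   at least 2.
#' @param v Numeric vector of values (HU), same length as `t`.
#' @return An object of class `time_curve`: a list with elements `t` and `v`.
#' @export
#' @examples
#' tc <- time_curve(seq(0, 60, by = 2), dgamma(seq(0, 60, by = 2), 3, 0.5))
#' curve_area(tc)
time_curve <- function(t, v) {
  t <- as.numeric(t)
  v <- as.numeric(v)
  if (length(t) != length(v)) {
    stop("time_curve: `t` and `v` must have equal length", call. = FALSE)
  }
  if (length(t) < 2L) {
    stop("time_curve: need at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(diff(t) <= 0)) {
    stop("time_curve: `t` must be finite and strictly increasing", call. = FALSE)
  }
  structure(list(t = t, v = v), class = "time_curve")
}

#' @export
print.time_curve <- function(x, ...) {
  cat(sprintf(
    "<time_curve> %d samples, t = [%g, %g] s, peak %.3g HU at t = %g s\n",
    length(x$t), x$t[1], x$t[length(x$t)], max(x$v), x$t[which.max(x$v)]
  ))
  invisible(x)
}

#' Trapezoidal area under a curve
#'
#' @param tc A [time_curve()], or a numeric vector of values when `t` is given.
#' @param t Optional time vector when `tc` is a plain numeric vector.
#' @return Trapezoidal integral (value units times seconds).
#' @export
curve_area <- function(tc, t = NULL) {
  if (inherits(tc, "time_curve")) {
    t <- tc$t
    v <- tc$v
  } else {
    v <- tc
    if (is.null(t)) stop("curve_area: `t` required for plain vectors", call. = FALSE)
  }
  trapz(t, v)
}

# Trapezoidal rule on possibly non-uniform abscissae.
trapz <- function(t, v) {
  n <- length(t)
  sum((t[-1] - t[-n]) * (v[-1] + v[-n])) / 2
}

# Linear interpolation of a curve onto a new time grid; values outside the
# sampled support are 0 (contrast has not arrived / baseline).
interp_curve <- function(tc, t_new) {
  stats::approx(tc$t, tc$v, xout = t_new, method = "linear",
                yleft = 0, yright = 0)$y
}

# Interpolation weight matrix W such that W %*% v resamples values sampled at
# `t_from` onto `t_to` (linear, zero outside). Used to resample many curves
# sharing one time axis with a single matrix product.
interp_matrix <- function(t_from, t_to) {
  n_from <- length(t_from)
  W <- matrix(0, nrow = length(t_to), ncol = n_from)
  idx <- findInterval(t_to, t_from)
  for (i in seq_along(t_to)) {
    j <- idx[i]
    if (j < 1L || j >= n_from) {
      if (j == n_from && t_to[i] == t_from[n_from]) W[i, n_from] <- 1
      next
    }
    w <- (t_to[i] - t_from[j]) / (t_from[j + 1L] - t_from[j])
    W[i, j] <- 1 - w
    W[i, j + 1L] <- w
  }
  W
}

# Round half away from zero (so 6.5 s -> 7 s, 12.5% -> 15%), unlike base
# round()'s banker's rounding.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Round to the nearest multiple of `step`, halfway up.
round_to_step <- function(x, step) {
  step * round_half_up(x / step)
}
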