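# Shared fixtures, built once per test run.

# Default synthetic arterial curve (the package's documented stand-in).
fix_aif <- make_arterial_tdc()

# Two-point regression fit: the closed forms only consume slope/intercept, so
# printed coefficients are injected exactly via a two-point line.
two_point_fit <- function(slope, intercept) {
  fit_regression(c(0, 50), c(intercept, intercept + 50 * slope))
}

# Independent bisection root-finder (oracle for the gamma shape exponent).
bisect_root <- function(f, lo, hi, tol = 1e-12) {
  stopifnot(f(lo) * f(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Fine-grid direct convolution oracle: conv of Ca with kernel values `h_fun(t)`
# evaluated on a 0.01 s grid, sampled back at `t_out`. Deliberately avoids the
# package's convolution path.
direct_conv_oracle <- function(Ca, h_fun, t_out, dt = 0.01) {
  t_fine <- seq(0, max(t_out), by = dt)
  ca <- stats::approx(Ca$t, Ca$v, xout = t_fine, yleft = 0, yright = 0)$y
  h <- h_fun(t_fine)
  y <- stats::convolve(ca, rev(h), type = "open")[seq_along(t_fine)] * dt
  stats::approx(t_fine, y, xout = t_out)$y
}

# Plain trapezoid (kept local so tests do not rely on package internals).
trapz_oracle <- function(t, v) {
  n <- length(t)
  sum((t[-1] - t[-n]) * (v[-1] + v[-n])) / 2
}
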