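#' Ground-truth perfusion parameters
#'
#' Construct a self-consistent set of ground-truth perfusion parameters from
#' the independent quantities (T0, MTT, CBV). CBF follows from the Central
#' Volume Principle, CBF = 60 * CBV / MTT (the factor 60 converts the
#' second-based MTT to the minute-based CBF unit), and Tmax follows the
#' model-based convention Tmax = T0 + MTT / 2.
#'
#' @param T0 Arterial-to-tissue arrival delay, s (>= 0).
#' @param MTT Mean transit time, s (> 0).
#' @param CBV Cerebral blood volume, ml/100 g (>= 0).
#' @return A `ground_truth` list with fields `CBF` (ml/min/100 g), `CBV`
#'   (ml/100 g), `MTT` (s), `T0` (s), `Tmax` (s).
#' @export
#' @examples
#' ground_truth(T0 = 0, MTT = 3.4, CBV = 5)$CBF  # 88.2 ml/min/100 g
ground_truth <- function(T0, MTT, CBV) {
  if (T0 < 0 || CBV < 0 || MTT <= 0) {
    stop("ground_truth: need T0 >= 0, CBV >= 0, MTT > 0", call. = FALSE)
  }
  structure(list(
    CBF = 60 * CBV / MTT,
    CBV = CBV,
    MTT = MTT,
    T0 = T0,
    Tmax = T0 + 0.5 * MTT
  ), class = "ground_truth")
}

#' Synthetic arterial time-density curve
#'
#' Generates an analytic arterial input function (AIF): a gamma-variate
#' first-pass bolus plus a smaller, delayed and dispersed recirculation bump.
#' This is a documented synthetic stand-in for a patient-measured arterial
#' curve; its shape parameters are configurable so the downstream calibration
#' can be repeated for other inputs.
#'
#' @param duration_s Total duration of the curve, s (>= 40).
#' @param dt_s Sampling interval, s (> 0).
#' @param bolus_arrival_s Time of contrast arrival in the artery, s.
#' @param peak_hu First-pass peak enhancement, HU.
#' @param shape Gamma-variate shape exponent of the first pass.
#' @param scale_s Gamma-variate time scale of the first pass, s.
#' @param recirc_weight Recirculation peak relative to the first-pass peak;
#'   0 disables recirculation.
#' @param recirc_delay_s Delay of the recirculation bolus after first-pass
#'   arrival, s.
#' @param recirc_broaden Dispersion factor applied to the recirculation time
#'   scale (> 1 means broader).
#' @return A [time_curve()] with baseline 0 before bolus arrival.
#' @export
make_arterial_tdc <- function(duration_s = 60, dt_s = 0.5,
                              bolus_arrival_s = 10, peak_hu = 250,
                              shape = 3, scale_s = 2.7,
                              recirc_weight = 0.25, recirc_delay_s = 15,
                              recirc_broaden = 2.5) {
  if (duration_s < 40) stop("make_arterial_tdc: duration_s must be >= 40 s", call. = FALSE)
  if (dt_s <= 0) stop("make_arterial_tdc: dt_s must be > 0", call. = FALSE)
  t <- seq(0, duration_s, by = dt_s)
  # unit-peak gamma variate: (t/mode)^a exp(a (1 - t/mode)), mode = a*b
  gv <- function(t, t0, a, b) {
    u <- pmax(t - t0, 0)
    mode <- a * b
    ifelse(u > 0, (u / mode)^a * exp(a * (1 - u / mode)), 0)
  }
  v <- peak_hu * gv(t, bolus_arrival_s, shape, scale_s)
  if (recirc_weight > 0) {
    v <- v + recirc_weight * peak_hu *
      gv(t, bolus_arrival_s + recirc_delay_s, shape, scale_s * recirc_broaden)
  }
  time_curve(t, v)
}

# Universal gamma-variate shape exponent: for a flow-scaled IRF
# K u^a exp(-u/b) constrained to have peak height CBF, area 60*CBV and mode
# at MTT/2 past T0, the Central Volume Principle forces
#   a * a^a exp(-a) / gamma(a + 1) = 1/2,
# independent of (CBF, CBV, MTT). Solved once and cached.
gamma_shape_exponent <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- function(a) a * exp(a * log(a) - a - lgamma(a + 1)) - 0.5
      cache <<- stats::uniroot(f, c(0.5, 50), tol = 1e-12)$root
    }
    cache
  }
})

#' Gamma-variate flow-scaled impulse residue function
#'
#' Builds the phantom's ground-truth flow-scaled IRF
#' \deqn{R_F(t) = K (t - T_0)^a e^{-(t - T_0)/b}, \quad t \ge T_0}
#' with (K, a, b) solved so that the peak height equals CBF (ml/min/100 g),
#' the trapezoidal area divided by 60 equals CBV (ml/100 g) and the time of
#' the peak equals T0 + MTT/2, the model-based Tmax convention. The shape
#' exponent `a` solving all three constraints simultaneously is the same for
#' every parameter combination (see [ground_truth()]).
#'
#' @param gt A [ground_truth()] object.
#' @param dt_s Sampling interval of the returned IRF, s (0.01 s recommended).
#' @param duration_s Duration to tabulate, s; defaults to T0 + 12 * MTT which
#'   captures > 99.9\% of the gamma tail.
#' @return A `flow_irf` list with fields `t` (s), `r` (ml/min/100 g), and the
#'   solved shape parameters `K`, `a`, `b`.
#' @export
make_gamma_variate_irf <- function(gt, dt_s = 0.01, duration_s = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (dt_s <= 0) stop("make_gamma_variate_irf: dt_s must be > 0", call. = FALSE)
  a <- gamma_shape_exponent()
  b <- gt$MTT / (2 * a)                      # mode a*b = MTT/2
  logK <- log(gt$CBF) - a * log(a * b) + a   # peak K (ab)^a e^-a = CBF
  if (is.null(duration_s)) duration_s <- gt$T0 + 12 * gt$MTT
  t <- seq(0, duration_s, by = dt_s)
  u <- pmax(t - gt$T0, 0)
  r <- ifelse(u > 0, exp(logK + a * log(u) - u / b), 0)
  area_cbv <- trapz(t, r) / 60
  if (abs(area_cbv - gt$CBV) > 1e-3 * max(gt$CBV, 1e-12)) {
    stop(sprintf(
      "make_gamma_variate_irf: IRF area %.5g ml/100 g deviates from CBV %.5g (decrease dt_s?)",
      area_cbv, gt$CBV
    ), call. = FALSE)
  }
  structure(list(t = t, r = r, K = exp(logK), a = a, b = b, gt = gt),
            class = "flow_irf")
}

#' Noise-free tissue time-density curve
#'
#' Convolves the arterial curve with a flow-scaled IRF to produce the tissue
#' curve of the indicator-dilution model Q(t) = C_a(t) (x) R_F(t). The
#' arterial curve is linearly interpolated to a fine simulation step (0.01 s),
#' discretely convolved with the IRF (scaled by the step, by 1/60 for the
#' min-to-s flow unit and by 1/100 for the per-100 g mass convention) and
#' resampled at the scanner interval.
#'
#' @param aif Arterial [time_curve()].
#' @param irf A `flow_irf` from [make_gamma_variate_irf()] (or any list with
#'   uniformly sampled `t`, `r`).
#' @param dt_sim_s Simulation step, s (default 0.01).
#' @param dt_out_s Output sampling interval, s (default 2, a typical CTP
#'   frame interval).
#' @param duration_s Output duration, s; defaults to the AIF duration.
#' @return A [time_curve()] sampled on `seq(0, duration_s, dt_out_s)`, HU.
#' @export
simulate_tissue_tdc <- function(aif, irf, dt_sim_s = 0.01, dt_out_s = 2,
                                duration_s = NULL) {
  stopifnot(inherits(aif, "time_curve"))
  if (is.null(duration_s)) duration_s <- aif$t[length(aif$t)]
  if (duration_s > aif$t[length(aif$t)] + 1e-9) {
    stop("simulate_tissue_tdc: requested duration exceeds AIF coverage", call. = FALSE)
  }
  t_fine <- seq(0, duration_s, by = dt_sim_s)
  ca <- interp_curve(aif, t_fine)
  r_fine <- stats::approx(irf$t, irf$r, xout = t_fine, yleft = 0, yright = 0)$y
  # open linear convolution, truncated to the scan window
  q_full <- stats::convolve(ca, rev(r_fine), type = "open")
  q_fine <- q_full[seq_along(t_fine)] * dt_sim_s / 6000
  t_out <- seq(0, duration_s, by = dt_out_s)
  v_out <- stats::approx(t_fine, q_fine, xout = t_out)$y
  time_curve(t_out, v_out)
}

#' Add Gaussian noise to a curve
#'
#' Adds independent zero-mean Gaussian perturbations to every sample,
#' emulating the residual noise of Gaussian-filtered dynamic CT images.
#'
#' @param tdc A [time_curve()].
#' @param sigma_hu Noise standard deviation, HU (>= 0); the phantom default
#'   is 1.5 HU.
#' @param n Number of independent noisy replicates.
#' @return For `n = 1`, a [time_curve()]; otherwise a matrix with one column
#'   per replicate (rows follow `tdc$t`).
#' @export
add_noise <- function(tdc, sigma_hu = 1.5, n = 1L) {
  stopifnot(inherits(tdc, "time_curve"))
  if (sigma_hu < 0) stop("add_noise: sigma_hu must be >= 0", call. = FALSE)
  m <- length(tdc$v)
  noise <- matrix(stats::rnorm(m * n, sd = sigma_hu), nrow = m, ncol = n)
  out <- tdc$v + noise
  if (n == 1L) time_curve(tdc$t, out[, 1L]) else out
}

#' Phantom configuration
#'
#' Default simulation grids and settings of the digital perfusion phantom.
#' The defaults are the published grids: 7 arrival delays x 7 mean transit
#' times x 8 blood volumes = 392 parameter combinations, 1024 noise
#' realizations per combination at sigma = 1.5 HU, tissue curves sampled at
#' 2 s over a 60 s scan simulated at a 0.01 s step.
#'
#' @param T0_grid Arrival delays, s.
#' @param MTT_grid Mean transit times, s.
#' @param CBV_grid Blood volumes, ml/100 g.
#' @param n_real Noise realizations per combination.
#' @param sigma_hu Tissue noise SD, HU.
#' @param duration_s Scan duration, s.
#' @param dt_sim_s Fine simulation step, s.
#' @param dt_out_s Tissue sampling interval, s.
#' @param aif Arterial [time_curve()]; default [make_arterial_tdc()] with its
#'   documented defaults.
#' @param aif_sigma_hu Optional Gaussian noise SD added to the arterial curve
#'   (0 keeps the AIF analytic and clean, the default).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(T0_grid = c(0, 0.5, 1, 2, 3, 4, 8),
                           MTT_grid = c(3.4, 4, 6, 8, 10, 12, 16),
                           CBV_grid = c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5),
                           n_real = 1024L,
                           sigma_hu = 1.5,
                           duration_s = 60,
                           dt_sim_s = 0.01,
                           dt_out_s = 2,
                           aif = NULL,
                           aif_sigma_hu = 0) {
  if (!length(T0_grid) || !length(MTT_grid) || !length(CBV_grid)) {
    stop("phantom_config: parameter grids must be non-empty", call. = FALSE)
  }
  if (n_real < 1L) stop("phantom_config: n_real must be >= 1", call. = FALSE)
  if (is.null(aif)) aif <- make_arterial_tdc(duration_s = duration_s)
  structure(list(
    T0_grid = T0_grid, MTT_grid = MTT_grid, CBV_grid = CBV_grid,
    n_real = as.integer(n_real), sigma_hu = sigma_hu,
    duration_s = duration_s, dt_sim_s = dt_sim_s, dt_out_s = dt_out_s,
    aif = aif, aif_sigma_hu = aif_sigma_hu
  ), class = "phantom_config")
}

#' Build the digital perfusion phantom
#'
#' Generates the full Cartesian product of the configured (T0, MTT, CBV)
#' grids; for each combination, simulates the noise-free tissue curve by
#' fine-step convolution of the arterial curve with the gamma-variate IRF and
#' draws `n_real` noisy realizations. Reproducible: each combination uses a
#' deterministic substream derived from the master seed, so realizations do
#' not depend on combination order.
#'
#' @param config A [phantom_config()].
#' @param seed Master integer seed.
#' @return A `phantom_dataset` list: `aif`, `combos` (data.frame of ground
#'   truth parameters, one row per combination), `t` (shared tissue time
#'   axis, s), `clean` (matrix, time x combo, noise-free curves),
#'   `curves` (list of time x n_real matrices of noisy curves),
#'   `sigma_hu`, `seed`, `config`.
#' @export
build_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- expand.grid(CBV = config$CBV_grid, MTT = config$MTT_grid,
                      T0 = config$T0_grid, KEEP.OUT.ATTRS = FALSE)
  combos <- data.frame(
    T0 = grid$T0, MTT = grid$MTT, CBV = grid$CBV,
    CBF = 60 * grid$CBV / grid$MTT,
    Tmax = grid$T0 + 0.5 * grid$MTT
  )
  aif <- config$aif
  if (config$aif_sigma_hu > 0) {
    set.seed(seed %% .Machine$integer.max)
    aif <- add_noise(aif, config$aif_sigma_hu)
  }
  n_combo <- nrow(combos)
  t_out <- seq(0, config$duration_s, by = config$dt_out_s)
  clean <- matrix(0, nrow = length(t_out), ncol = n_combo)
  curves <- vector("list", n_combo)
  for (i in seq_len(n_combo)) {
    gt <- ground_truth(combos$T0[i], combos$MTT[i], combos$CBV[i])
    irf <- make_gamma_variate_irf(gt, dt_s = config$dt_sim_s)
    tdc <- simulate_tissue_tdc(aif, irf, dt_sim_s = config$dt_sim_s,
                               dt_out_s = config$dt_out_s,
                               duration_s = config$duration_s)
    clean[, i] <- tdc$v
    # per-combo substream: independent of combo evaluation order
    set.seed((seed * 1000003L + i) %% .Machine$integer.max)
    noisy <- add_noise(tdc, config$sigma_hu, n = config$n_real)
    curves[[i]] <- if (inherits(noisy, "time_curve")) matrix(noisy$v, ncol = 1) else noisy
  }
  structure(list(
    aif = aif, combos = combos, t = t_out, clean = clean, curves = curves,
    sigma_hu = config$sigma_hu, seed = as.integer(seed), config = config
  ), class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf(
    "<phantom_dataset> %d combos x %d realizations, %d frames at %g s, sigma = %g HU, seed %d\n",
    nrow(x$combos), ncol(x$curves[[1]]), length(x$t),
    x$config$dt_out_s, x$sigma_hu, x$seed
  ))
  invisible(x)
}

#' Export phantom curves as a long table
#'
#' Flattens a phantom into a data.frame suitable for CSV export: one row per
#' (combo, realization, time sample).
#'
#' @param phantom A `phantom_dataset` from [build_phantom()].
#' @param max_real Cap on realizations exported per combo (tables get large).
#' @return A data.frame with ground-truth columns, `real`, `t_s`, `hu`.
#' @export
phantom_to_table <- function(phantom, max_real = Inf) {
  stopifnot(inherits(phantom, "phantom_dataset"))
  n_r <- min(ncol(phantom$curves[[1]]), max_real)
  n_t <- length(phantom$t)
  pieces <- lapply(seq_len(nrow(phantom$combos)), function(i) {
    cbind(
      phantom$combos[rep(i, n_r * n_t), , drop = FALSE],
      real = rep(seq_len(n_r), each = n_t),
      t_s = rep(phantom$t, n_r),
      hu = as.vector(phantom$curves[[i]][, seq_len(n_r)])
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
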