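# Deconvolution engines
#
# All engines work on a 1 s virtual sampling grid and share the unit
# convention: tissue and arterial curves are HU (proportional concentration,
# tissue density 1 g/ml), flow-scaled IRF values are ml/min/100 g. With a
# 1 s time step the discrete model Q = F_hat * basis has F_hat in units of
# 1/s per gram, so CBF = 60 * 100 * F_hat.

FLOW_UNIT_SCALE <- 6000  # 60 s/min * 100 g

#' Perfusion estimate
#'
#' Container for engine output. Model-based engines satisfy
#' Tmax = T0 + MTT/2 and CBV = CBF * MTT / 60 exactly; the model-independent
#' engine leaves `T0` as `NA` and derives MTT = 60 * CBV / CBF.
#'
#' @param CBF ml/min/100 g. @param CBV ml/100 g. @param MTT s. @param T0 s.
#' @param Tmax s. @param sse model-fit residual sum of squares (model-based
#'   engines). @param degenerate flag for all-zero input fits.
#' @return A `perfusion_estimate` list.
#' @export
perfusion_estimate <- function(CBF, CBV, MTT, Tmax, T0 = NA_real_,
                               sse = NA_real_, degenerate = FALSE) {
  structure(list(CBF = CBF, CBV = CBV, MTT = MTT, T0 = T0, Tmax = Tmax,
                 sse = sse, degenerate = degenerate),
            class = "perfusion_estimate")
}

#' @export
print.perfusion_estimate <- function(x, ...) {
  cat(sprintf(
    "<perfusion_estimate> CBF %.2f ml/min/100g  CBV %.3f ml/100g  MTT %.2f s  T0 %s  Tmax %.2f s%s\n",
    x$CBF, x$CBV, x$MTT, ifelse(is.na(x$T0), "-", sprintf("%.1f s", x$T0)),
    x$Tmax, if (isTRUE(x$degenerate)) "  [degenerate]" else ""
  ))
  invisible(x)
}

# Common 1 s working grid for a pair of curves (shared duration).
working_grid <- function(Q, Ca) {
  dur <- min(Q$t[length(Q$t)], Ca$t[length(Ca$t)])
  seq(0, floor(dur), by = 1)
}

## ---------------------------------------------------------------------------
## Model-independent (Fourier) engine

# Vectorized core: qmat is an nt x nvox matrix of tissue curves already on the
# 1 s grid; ca is the arterial curve on the same grid. Returns per-voxel CBF,
# Tmax, CBV and the estimated flow-scaled IRF matrix.
fourier_core <- function(qmat, ca, t_grid, reg_frac = 0.2) {
  n <- length(ca)
  np <- 2L * n  # zero-pad to twice the length to avoid time aliasing
  ca_pad <- c(ca, rep(0, np - n))
  Fa <- stats::fft(ca_pad)
  lam <- reg_frac * max(Mod(Fa))
  denom <- Mod(Fa)^2 + lam^2
  q_pad <- rbind(qmat, matrix(0, np - n, ncol(qmat)))
  Fq <- stats::mvfft(q_pad)
  H <- Fq * Conj(Fa) / denom
  rf <- Re(stats::mvfft(H, inverse = TRUE)) / np   # per-second, HU-normalized
  rf_phys <- rf * FLOW_UNIT_SCALE                  # ml/min/100 g
  # search the unpadded half: physical Tmax lies within the scan window
  rf_win <- rf_phys[seq_len(n), , drop = FALSE]
  peak_idx <- max.col(t(rf_win), ties.method = "first")
  cbf <- rf_win[cbind(peak_idx, seq_len(ncol(rf_win)))]
  tmax <- t_grid[peak_idx]
  area_ca <- trapz(t_grid, ca)
  area_q <- apply(qmat, 2, function(v) trapz(t_grid, v))
  cbv <- 100 * area_q / area_ca
  list(cbf = pmax(cbf, 0), cbv = pmax(cbv, 0), tmax = tmax, irf = rf_phys)
}

#' Model-independent Fourier deconvolution
#'
#' Estimates the flow-scaled IRF by regularized Fourier deconvolution: both
#' curves are linearly interpolated to a 1 s virtual sampling interval and
#' zero-padded to twice their length (circulant convolution, hence
#' delay-insensitive); the naive spectral quotient is stabilized by a
#' Wiener-like filter with threshold `reg_frac` (default 20\%) relative to
#' the maximum magnitude of the arterial spectrum:
#' \deqn{\hat R_F = \mathcal{F}^{-1}\{ \mathcal{F}Q \cdot
#'   \overline{\mathcal{F}C_a} / (|\mathcal{F}C_a|^2 + \lambda^2) \},
#'   \quad \lambda = \mathrm{reg\_frac} \cdot \max|\mathcal{F}C_a|.}
#' CBF is the peak of the estimated IRF and Tmax its argmax time (1 s
#' resolution); CBV is 100 times the ratio of raw trapezoidal curve areas
#' (ml/100 g); MTT = 60 CBV / CBF by the Central Volume Principle.
#'
#' @param Q Tissue [time_curve()]. @param Ca Arterial [time_curve()].
#' @param reg_frac Regularization fraction in (0, 1).
#' @return List with `irf` (estimated flow-scaled IRF as [time_curve()], on
#'   the padded axis) and `est` ([perfusion_estimate()]).
#' @export
deconvolve_fourier <- function(Q, Ca, reg_frac = 0.2) {
  stopifnot(inherits(Q, "time_curve"), inherits(Ca, "time_curve"))
  if (reg_frac <= 0 || reg_frac >= 1) {
    stop("deconvolve_fourier: reg_frac must be in (0, 1)", call. = FALSE)
  }
  t_grid <- working_grid(Q, Ca)
  ca <- interp_curve(Ca, t_grid)
  if (trapz(t_grid, ca) <= 0) {
    stop("deconvolve_fourier: arterial curve has non-positive area", call. = FALSE)
  }
  # CBV from raw (uninterpolated) curve areas
  area_ratio <- curve_area(Q) / curve_area(Ca)
  q <- interp_curve(Q, t_grid)
  core <- fourier_core(matrix(q, ncol = 1), ca, t_grid, reg_frac)
  cbf <- core$cbf[1]
  cbv <- max(100 * area_ratio, 0)
  est <- perfusion_estimate(
    CBF = cbf, CBV = cbv,
    MTT = if (cbf > 0) 60 * cbv / cbf else Inf,
    Tmax = core$tmax[1]
  )
  n_pad <- nrow(core$irf)
  list(irf = time_curve(seq_len(n_pad) - 1, core$irf[, 1]), est = est)
}

## ---------------------------------------------------------------------------
## Model-dependent (plug-flow) engine

#' Plug-flow grid
#'
#' Candidate (T0, MTT) pairs searched by the plug-flow engine. The default is
#' the published grid: T0 in 0..24 s and MTT in 2..24 s at 1 s steps, i.e.
#' 25 x 23 = 575 combinations. Pairs are ordered by T0 then MTT so that SSE
#' ties resolve to the smallest T0, then smallest MTT.
#'
#' @param T0_values Delays, s. @param MTT_values Transit times, s.
#' @return A `plugflow_grid` data.frame with columns `T0`, `MTT`.
#' @export
plugflow_grid <- function(T0_values = 0:24, MTT_values = 2:24) {
  if (!length(T0_values) || !length(MTT_values) ||
      any(T0_values < 0) || any(MTT_values <= 0)) {
    stop("plugflow_grid: grids must be non-empty and non-negative", call. = FALSE)
  }
  g <- expand.grid(MTT = sort(as.numeric(MTT_values)),
                   T0 = sort(as.numeric(T0_values)), KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(T0 = g$T0, MTT = g$MTT)
  class(out) <- c("plugflow_grid", "data.frame")
  out
}

#' Plug-flow model basis curve
#'
#' The closed-form tissue response of a unit-flow plug-flow (boxcar) IRF with
#' delay `T0` and transit time `MTT`:
#' \deqn{b(t) = \int_0^t C_a(u - T_0)\,du - \int_0^t C_a(u - T_0 - MTT)\,du,}
#' equivalently the convolution of the arterial curve with a unit boxcar on
#' [T0, T0 + MTT). Computed by trapezoidal integration on a 1 s working grid;
#' the arterial curve is treated as 0 before its first sample.
#'
#' @param Ca Arterial [time_curve()]. @param T0 Delay, s. @param MTT Transit
#'   time, s.
#' @return A [time_curve()] on the 1 s grid, units HU * s.
#' @export
plugflow_basis <- function(Ca, T0, MTT) {
  stopifnot(inherits(Ca, "time_curve"))
  if (T0 < 0 || MTT <= 0) stop("plugflow_basis: need T0 >= 0, MTT > 0", call. = FALSE)
  t_grid <- seq(0, floor(Ca$t[length(Ca$t)]), by = 1)
  b <- plugflow_basis_values(Ca, t_grid, T0, MTT)
  time_curve(t_grid, b)
}

plugflow_basis_values <- function(Ca, t_grid, T0, MTT) {
  shifted_cum <- function(delay) {
    v <- interp_curve(Ca, t_grid - delay)
    cumtrapz(t_grid, v)
  }
  shifted_cum(T0) - shifted_cum(T0 + MTT)
}

cumtrapz <- function(t, v) {
  n <- length(t)
  c(0, cumsum((t[-1] - t[-n]) * (v[-1] + v[-n]) / 2))
}

# Precompute the basis matrix (nt x npairs) and Gram quantities for a grid.
plugflow_design <- function(Ca, t_grid, grid) {
  B <- vapply(seq_len(nrow(grid)),
              function(i) plugflow_basis_values(Ca, t_grid, grid$T0[i], grid$MTT[i]),
              numeric(length(t_grid)))
  list(B = B, bb = colSums(B^2), grid = grid)
}

# Vectorized plug-flow fit: qmat nt x nvox on the design's grid.
plugflow_core <- function(qmat, design) {
  num <- crossprod(design$B, qmat)             # npairs x nvox
  f <- pmax(num / design$bb, 0)                # single-coefficient NNLS
  qq <- colSums(qmat^2)
  sse <- -2 * f * num + f^2 * design$bb        # + qq, constant per voxel
  best <- max.col(t(-sse), ties.method = "first")
  j <- seq_len(ncol(qmat))
  f_best <- f[cbind(best, j)]
  list(
    T0 = design$grid$T0[best],
    MTT = design$grid$MTT[best],
    F = f_best,
    sse = sse[cbind(best, j)] + qq,
    n_pairs = nrow(design$grid)
  )
}

#' Model-dependent plug-flow deconvolution
#'
#' Grid search over (T0, MTT) pairs: for each pair the basis curve of
#' [plugflow_basis()] is fit to the tissue curve by single-coefficient
#' non-negative least squares, linearizing the CBF estimate; the pair with
#' the least squared residual wins (ties: smallest T0, then smallest MTT).
#' CBF = 6000 * F_hat (ml/min/100 g), CBV = CBF * MTT / 60 by the Central
#' Volume Principle, Tmax = T0 + MTT/2.
#'
#' @param Q Tissue [time_curve()]. @param Ca Arterial [time_curve()].
#' @param grid A [plugflow_grid()].
#' @return A [perfusion_estimate()]; `attr(, "n_pairs")` records the number
#'   of candidate pairs evaluated.
#' @export
deconvolve_plugflow <- function(Q, Ca, grid = plugflow_grid()) {
  stopifnot(inherits(Q, "time_curve"), inherits(Ca, "time_curve"))
  t_grid <- working_grid(Q, Ca)
  design <- plugflow_design(Ca, t_grid, grid)
  q <- interp_curve(Q, t_grid)
  fit <- plugflow_core(matrix(q, ncol = 1), design)
  degenerate <- all(q == 0) || fit$F[1] == 0
  cbf <- FLOW_UNIT_SCALE * fit$F[1]
  est <- perfusion_estimate(
    CBF = cbf, CBV = cbf * fit$MTT[1] / 60, MTT = fit$MTT[1],
    T0 = fit$T0[1], Tmax = fit$T0[1] + 0.5 * fit$MTT[1],
    sse = fit$sse[1], degenerate = degenerate
  )
  attr(est, "n_pairs") <- fit$n_pairs
  est
}

## ---------------------------------------------------------------------------
## Johnson-Wilson-Lee (JWL) model engine

#' Johnson-Wilson-Lee flow-scaled IRF
#'
#' The JWL impulse residue function: a plateau of height 1 for the minimum
#' transit time `W` followed by an exponential tail of initial height `E`
#' (the fraction of contrast with transit time > W) decaying at rate `k`,
#' delayed by `T0` and scaled by the flow `F`:
#' \deqn{R(t) = 1 \ \mathrm{on}\ [T_0, T_0+W), \quad
#'       E e^{-k (t - T_0 - W)} \ \mathrm{for}\ t \ge T_0 + W.}
#' MTT is the area under the unit-height IRF, W + E/k.
#'
#' @param T0 Delay, s. @param W Minimum transit time, s. @param E Fraction in
#'   (0, 1]. @param k Decay rate, 1/s (> 0). @param F Flow, ml/min/100 g.
#' @param dt_s Sampling step, s. @param duration_s Tabulation length, s.
#' @return A `flow_irf` list with `t`, `r` and the derived `MTT`, `Tmax`.
#' @export
jwl_irf <- function(T0, W, E, k, F = 60, dt_s = 0.01, duration_s = NULL) {
  if (k <= 0) stop("jwl_irf: k must be > 0", call. = FALSE)
  if (E < 0 || E > 1) stop("jwl_irf: E must be in [0, 1]", call. = FALSE)
  if (W <= 0 || T0 < 0) stop("jwl_irf: need W > 0, T0 >= 0", call. = FALSE)
  mtt <- W + E / k
  if (is.null(duration_s)) duration_s <- T0 + W + 15 / k
  t <- seq(0, duration_s, by = dt_s)
  r <- numeric(length(t))
  r[t >= T0 & t < T0 + W] <- 1
  tail <- t >= T0 + W
  r[tail] <- E * exp(-k * (t[tail] - T0 - W))
  structure(list(t = t, r = F * r, MTT = mtt, Tmax = T0 + 0.5 * mtt,
                 T0 = T0, W = W, E = E, k = k, F = F),
            class = "flow_irf")
}

#' JWL grid
#'
#' Candidate (T0, W, k) triples for the JWL grid-search engine. Defaults
#' mirror the plug-flow grid in T0 and plateau width, with a geometric ladder
#' of decay rates. Triples are ordered by T0, then W, then k for
#' deterministic tie-breaking.
#'
#' @param T0_values s. @param W_values s. @param k_values 1/s.
#' @return A `jwl_grid` data.frame with columns `T0`, `W`, `k`.
#' @export
jwl_grid <- function(T0_values = 0:24, W_values = 2:24,
                     k_values = c(0.1, 0.2, 0.4, 0.8, 1.6)) {
  if (any(k_values <= 0)) stop("jwl_grid: k values must be > 0", call. = FALSE)
  g <- expand.grid(k = sort(as.numeric(k_values)),
                   W = sort(as.numeric(W_values)),
                   T0 = sort(as.numeric(T0_values)), KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(T0 = g$T0, W = g$W, k = g$k)
  class(out) <- c("jwl_grid", "data.frame")
  out
}

# Convolution of a piecewise-linear curve with exp(-k t): exact per-segment
# exponential integrator, y(s) = integral_0^s ca(s - v) exp(-k v) dv.
exp_conv <- function(ca, k, dt) {
  n <- length(ca)
  ek <- exp(-k * dt)
  i0 <- (1 - ek) / k
  i1 <- dt / k - (1 - ek) / k^2
  w_prev <- i0 - i1 / dt
  w_next <- i1 / dt
  y <- numeric(n)
  for (j in 2:n) {
    y[j] <- y[j - 1] * ek + ca[j - 1] * w_prev + ca[j] * w_next
  }
  y
}

# Precompute JWL design: plateau basis per (T0, W) and tail basis per
# (T0, W, k), plus Gram quantities. The exponential tail basis is the
# k-specific exponential convolution of the arterial curve shifted by
# T0 + W (exact for piecewise-linear curves, so on-grid self-recovery is
# not tipped by quadrature error across the tail's onset).
jwl_design <- function(Ca, t_grid, grid) {
  ca <- interp_curve(Ca, t_grid)
  nt <- length(t_grid)
  dt <- t_grid[2] - t_grid[1]
  n3 <- nrow(grid)
  B1 <- matrix(0, nt, n3)
  B2 <- matrix(0, nt, n3)
  pw_cache <- new.env(parent = emptyenv())
  yk_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n3)) {
    key <- paste(grid$T0[i], grid$W[i])
    if (is.null(pw_cache[[key]])) {
      pw_cache[[key]] <- plugflow_basis_values(Ca, t_grid, grid$T0[i], grid$W[i])
    }
    B1[, i] <- pw_cache[[key]]
    kkey <- as.character(grid$k[i])
    if (is.null(yk_cache[[kkey]])) {
      yk_cache[[kkey]] <- exp_conv(ca, grid$k[i], dt)
    }
    B2[, i] <- stats::approx(t_grid, yk_cache[[kkey]],
                             xout = t_grid - grid$T0[i] - grid$W[i],
                             yleft = 0, yright = 0)$y
  }
  list(B1 = B1, B2 = B2,
       g11 = colSums(B1^2), g12 = colSums(B1 * B2), g22 = colSums(B2^2),
       grid = grid)
}

# Vectorized JWL fit. Two-coefficient NNLS (coefficients F and F*E) solved in
# closed form per (triple, voxel): unconstrained 2x2 solve, then boundary
# candidates when a coefficient is negative, then the E <= 1 clamp (refit F
# on the summed basis).
jwl_core <- function(qmat, design) {
  r1 <- crossprod(design$B1, qmat)   # n3 x nvox
  r2 <- crossprod(design$B2, qmat)
  g11 <- design$g11; g12 <- design$g12; g22 <- design$g22
  det <- g11 * g22 - g12^2
  det[det <= 0] <- NA  # collinear bases: fall back to boundary fits
  c1 <- (g22 * r1 - g12 * r2) / det
  c2 <- (g11 * r2 - g12 * r1) / det
  bad <- !is.finite(c1) | !is.finite(c2) | c1 < 0 | c2 < 0
  if (any(bad)) {
    # boundary candidates: tail-only is unphysical (plateau height F must
    # carry the flow), so drop the tail first; keep tail-only as last resort
    a1 <- pmax(r1 / g11, 0)                 # c2 = 0
    a2 <- pmax(r2 / g22, 0)                 # c1 = 0
    sse1 <- -2 * a1 * r1 + a1^2 * g11
    sse2 <- -2 * a2 * r2 + a2^2 * g22
    use1 <- sse1 <= sse2
    c1[bad] <- ifelse(use1[bad], a1[bad], 0)
    c2[bad] <- ifelse(use1[bad], 0, a2[bad])
  }
  # clamp E = c2/c1 <= 1: refit on the summed basis (E = 1 exactly)
  viol <- c2 > c1
  if (any(viol)) {
    gs <- g11 + 2 * g12 + g22
    cs <- pmax((r1 + r2) / gs, 0)
    c1[viol] <- cs[viol]
    c2[viol] <- cs[viol]
  }
  sse <- -2 * (c1 * r1 + c2 * r2) + c1^2 * g11 + 2 * c1 * c2 * g12 + c2^2 * g22
  best <- max.col(t(-sse), ties.method = "first")
  j <- seq_len(ncol(qmat))
  idx <- cbind(best, j)
  f <- c1[idx]
  e <- ifelse(f > 0, pmin(c2[idx] / f, 1), 0)
  list(
    T0 = design$grid$T0[best], W = design$grid$W[best], k = design$grid$k[best],
    F = f, E = e,
    sse = sse[idx] + colSums(qmat^2)
  )
}

#' JWL model-based deconvolution
#'
#' Grid-search engine fitting the Johnson-Wilson-Lee IRF ([jwl_irf()]) to a
#' tissue curve: for every (T0, W, k) triple the tissue curve is modelled as
#' F times the plateau basis plus F*E times the exponential-tail basis (both
#' trapezoidal convolutions of the arterial curve), solved by two-coefficient
#' non-negative least squares with the physiological constraint E <= 1
#' (clamped and refit when violated). The minimum-SSE triple wins.
#' MTT = W + E/k, Tmax = T0 + MTT/2, CBV = CBF * MTT / 60. This engine
#' emulates a commercial JWL-based method whose internals are unpublished.
#'
#' @param Q Tissue [time_curve()]. @param Ca Arterial [time_curve()].
#' @param grid A [jwl_grid()].
#' @return A [perfusion_estimate()] with extra fields `W`, `E`, `k` attached
#'   as attributes `jwl`.
#' @export
deconvolve_jwl <- function(Q, Ca, grid = jwl_grid()) {
  stopifnot(inherits(Q, "time_curve"), inherits(Ca, "time_curve"))
  t_grid <- working_grid(Q, Ca)
  design <- jwl_design(Ca, t_grid, grid)
  q <- interp_curve(Q, t_grid)
  fit <- jwl_core(matrix(q, ncol = 1), design)
  cbf <- FLOW_UNIT_SCALE * fit$F[1]
  mtt <- fit$W[1] + fit$E[1] / fit$k[1]
  est <- perfusion_estimate(
    CBF = cbf, CBV = cbf * mtt / 60, MTT = mtt,
    T0 = fit$T0[1], Tmax = fit$T0[1] + 0.5 * mtt,
    sse = fit$sse[1], degenerate = all(q == 0) || fit$F[1] == 0
  )
  attr(est, "jwl") <- list(W = fit$W[1], E = fit$E[1], k = fit$k[1])
  est
}

## ---------------------------------------------------------------------------
## Batch driver over a phantom dataset

#' Run a deconvolution engine over a phantom dataset
#'
#' Applies the named engine to every noisy realization of every parameter
#' combination in a phantom, using the phantom's arterial curve. Vectorized
#' per combination (realizations share the time axis).
#'
#' @param phantom A `phantom_dataset` from [build_phantom()].
#' @param engine One of `"mi"` (model-independent Fourier), `"md"`
#'   (model-dependent plug-flow) or `"jwl"`.
#' @param reg_frac Regularization fraction for `"mi"`.
#' @param grid Search grid for `"md"` / `"jwl"` (defaults per engine).
#' @return A data.frame with one row per (combo, realization): ground truth
#'   columns prefixed `gt_`, plus estimated `CBF`, `CBV`, `MTT`, `Tmax`.
#' @export
deconvolve_phantom <- function(phantom, engine = c("mi", "md", "jwl"),
                               reg_frac = 0.2, grid = NULL) {
  stopifnot(inherits(phantom, "phantom_dataset"))
  engine <- match.arg(engine)
  t_raw <- phantom$t
  t_grid <- seq(0, floor(t_raw[length(t_raw)]), by = 1)
  W <- interp_matrix(t_raw, t_grid)
  ca_tc <- phantom$aif
  ca <- interp_curve(ca_tc, t_grid)
  area_ca <- trapz(t_raw, interp_curve(ca_tc, t_raw))
  design <- switch(engine,
    mi = NULL,
    md = plugflow_design(ca_tc, t_grid, if (is.null(grid)) plugflow_grid() else grid),
    jwl = jwl_design(ca_tc, t_grid, if (is.null(grid)) jwl_grid() else grid)
  )
  n_combo <- nrow(phantom$combos)
  res <- vector("list", n_combo)
  for (i in seq_len(n_combo)) {
    qraw <- phantom$curves[[i]]
    qmat <- W %*% qraw
    if (engine == "mi") {
      core <- fourier_core(qmat, ca, t_grid, reg_frac)
      area_q <- colSums((qraw[-1, , drop = FALSE] + qraw[-nrow(qraw), , drop = FALSE]) / 2 *
                          diff(t_raw))
      cbv <- pmax(100 * area_q / area_ca, 0)
      cbf <- core$cbf
      out <- data.frame(CBF = cbf, CBV = cbv,
                        MTT = ifelse(cbf > 0, 60 * cbv / cbf, Inf),
                        Tmax = core$tmax)
    } else if (engine == "md") {
      fit <- plugflow_core(qmat, design)
      cbf <- FLOW_UNIT_SCALE * fit$F
      out <- data.frame(CBF = cbf, CBV = cbf * fit$MTT / 60, MTT = fit$MTT,
                        Tmax = fit$T0 + 0.5 * fit$MTT)
    } else {
      fit <- jwl_core(qmat, design)
      cbf <- FLOW_UNIT_SCALE * fit$F
      mtt <- fit$W + fit$E / fit$k
      out <- data.frame(CBF = cbf, CBV = cbf * mtt / 60, MTT = mtt,
                        Tmax = fit$T0 + 0.5 * mtt)
    }
    gt <- phantom$combos[rep(i, nrow(out)), , drop = FALSE]
    names(gt) <- paste0("gt_", names(gt))
    out <- cbind(gt, combo = i, real = seq_len(nrow(out)), out)
    res[[i]] <- out
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
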