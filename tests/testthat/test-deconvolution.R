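test_that("fourier: forward circulant simulation inverts within 2%", {
  # compactly supported pair so that truncating the linear convolution to the
  # scan window loses nothing and open == circulant convolution
  aif <- make_arterial_tdc(duration_s = 60, recirc_weight = 0,
                           bolus_arrival_s = 5, scale_s = 1.5)
  t_grid <- 0:60
  ca <- stats::approx(aif$t, aif$v, xout = t_grid, yleft = 0, yright = 0)$y
  gt <- ground_truth(0, 4, 2)
  irf <- make_gamma_variate_irf(gt, dt_s = 0.01)
  rf <- stats::approx(irf$t, irf$r, xout = t_grid, yleft = 0, yright = 0)$y
  # on-grid forward convolution (1 s step, the engine's own discretization)
  q <- stats::convolve(ca, rev(rf), type = "open")[seq_along(t_grid)] / 6000
  out <- deconvolve_fourier(time_curve(t_grid, q), time_curve(t_grid, ca),
                            reg_frac = 1e-4)
  expect_equal(out$est$CBF, max(rf), tolerance = 0.02)
  expect_equal(out$est$Tmax, t_grid[which.max(rf)], tolerance = 1.01)
})

test_that("fourier: scaled-copy CBV identity and degenerate guards", {
  aif <- fix_aif
  q <- time_curve(aif$t, 0.03 * aif$v)
  out <- deconvolve_fourier(q, aif)
  expect_equal(out$est$CBV, 3, tolerance = 1e-12)
  expect_equal(out$est$MTT, 60 * out$est$CBV / out$est$CBF)
  expect_error(deconvolve_fourier(q, time_curve(aif$t, rep(0, length(aif$t)))),
               "non-positive area")
  expect_error(deconvolve_fourier(q, aif, reg_frac = 0), "reg_frac")
})

test_that("fourier: delay shift moves Tmax, leaves CBF nearly unchanged", {
  aif <- fix_aif
  gt <- ground_truth(0, 6, 3)
  q0 <- simulate_tissue_tdc(aif, make_gamma_variate_irf(gt), dt_out_s = 1)
  base <- deconvolve_fourier(q0, aif)
  for (d in c(3, 7)) {
    qd <- time_curve(q0$t, stats::approx(q0$t, q0$v, xout = q0$t - d,
                                         yleft = 0, yright = 0)$y)
    shifted <- deconvolve_fourier(qd, aif)
    expect_lte(abs(shifted$est$Tmax - base$est$Tmax - d), 1)
    expect_equal(shifted$est$CBF, base$est$CBF, tolerance = 0.01)
  }
})

test_that("plug-flow basis matches direct boxcar convolution within 0.5%", {
  aif <- fix_aif
  for (p in list(c(0, 4), c(3, 8), c(10, 2))) {
    b <- plugflow_basis(aif, T0 = p[1], MTT = p[2])
    oracle <- direct_conv_oracle(
      aif, function(t) as.numeric(t >= p[1] & t < p[1] + p[2]), b$t
    )
    expect_lt(max(abs(b$v - oracle)), 0.005 * max(oracle))
    expect_true(all(b$v >= -1e-9))
  }
})

test_that("plug-flow basis: rectangle arterial curve ramps then plateaus", {
  # trapezoidal unit rectangle (1 s rise, top on [1, 10]): the piecewise
  # closed form gives cumint C(t) = t - 1/2 on [1, 10], so the basis ramps
  # over ~MTT and plateaus at exactly MTT
  t <- seq(0, 30)
  ca <- time_curve(t, as.numeric(t >= 1 & t <= 10))
  b <- plugflow_basis(ca, T0 = 0, MTT = 4)
  expect_equal(b$v[b$t == 2], 1.5, tolerance = 1e-9)
  expect_equal(b$v[b$t %in% 5:10], rep(4, 6), tolerance = 1e-9)
  # MTT beyond scan end: equals running integral of the shifted curve
  blong <- plugflow_basis(ca, T0 = 2, MTT = 100)
  shifted <- stats::approx(ca$t, ca$v, xout = blong$t - 2, yleft = 0, yright = 0)$y
  run_int <- c(0, cumsum((shifted[-1] + shifted[-length(shifted)]) / 2))
  expect_equal(blong$v, run_int, tolerance = 1e-9)
})

test_that("plug-flow engine: 575 pairs, on-grid self-recovery, argmin", {
  aif <- fix_aif
  t_fine <- seq(0, 40, 0.01)
  irf <- list(t = t_fine, r = ifelse(t_fine >= 3 & t_fine < 11, 30, 0))
  q <- simulate_tissue_tdc(aif, irf, dt_out_s = 1)
  est <- deconvolve_plugflow(q, aif)
  expect_identical(attr(est, "n_pairs"), 575L)
  expect_identical(est$T0, 3)
  expect_identical(est$MTT, 8)
  expect_equal(est$CBF, 30, tolerance = 0.01)
  expect_identical(est$Tmax, 7)
  expect_equal(est$CBV, est$CBF * est$MTT / 60)

  # exhaustiveness: winning SSE <= SSE of every other pair, by re-scan
  grid <- plugflow_grid()
  t_grid <- 0:min(floor(max(q$t)), floor(max(aif$t)))
  qv <- stats::approx(q$t, q$v, xout = t_grid, yleft = 0, yright = 0)$y
  sse_scan <- vapply(seq_len(nrow(grid)), function(i) {
    b <- plugflow_basis(aif, grid$T0[i], grid$MTT[i])$v[seq_along(t_grid)]
    f <- max(0, sum(qv * b) / sum(b^2))
    sum((qv - f * b)^2)
  }, numeric(1))
  expect_lte(est$sse, min(sse_scan) + 1e-9)

  # degenerate all-zero input
  z <- deconvolve_plugflow(time_curve(q$t, rep(0, length(q$t))), aif)
  expect_identical(z$CBF, 0)
  expect_true(z$degenerate)
})

test_that("jwl IRF: shape, area, Tmax convention", {
  p <- jwl_irf(T0 = 0, W = 4, E = 0.5, k = 0.25, F = 1, duration_s = 120)
  expect_equal(p$MTT, 6)
  expect_equal(trapz_oracle(p$t, p$r), 6, tolerance = 1e-3)
  expect_equal(p$Tmax, 0 + 0.5 * 6)
  # plateau of height F on [T0, T0+W)
  expect_true(all(p$r[p$t >= 0 & p$t < 4] == 1))
  # E = 1, large k approaches the plug-flow boxcar (area -> W as k grows);
  # fine dt because the trapezoid has a dt/2 edge error at the T0 jump
  box <- jwl_irf(T0 = 2, W = 5, E = 1, k = 20, F = 1, dt_s = 0.001)
  expect_equal(trapz_oracle(box$t, box$r), 5 + 1 / 20, tolerance = 1e-3)
  expect_error(jwl_irf(T0 = 0, W = 4, E = 0.5, k = 0), "k must be")
  expect_error(jwl_irf(T0 = 0, W = 4, E = 1.2, k = 1), "E must be")
})

test_that("jwl engine: on-grid self-recovery and E constraint", {
  aif <- fix_aif
  cases <- list(c(3, 6, 0.5, 0.4, 40), c(5, 10, 0.8, 0.2, 25), c(0, 4, 1, 0.8, 60))
  for (p in cases) {
    irf <- jwl_irf(T0 = p[1], W = p[2], E = p[3], k = p[4], F = p[5])
    q <- simulate_tissue_tdc(aif, irf, dt_out_s = 1)
    est <- deconvolve_jwl(q, aif)
    jw <- attr(est, "jwl")
    expect_identical(est$T0, p[1])
    expect_identical(jw$W, p[2])
    expect_identical(jw$k, p[4])
    expect_equal(jw$E, p[3], tolerance = 0.02)
    expect_equal(est$CBF, p[5], tolerance = 0.02)
    expect_gte(jw$E, 0); expect_lte(jw$E, 1)
    expect_equal(est$Tmax, est$T0 + 0.5 * est$MTT)
    expect_equal(est$CBV, est$CBF * est$MTT / 60)
  }
})

test_that("jwl engine: plug-flow input is recovered with a null tail", {
  aif <- fix_aif
  t_fine <- seq(0, 40, 0.01)
  irf <- list(t = t_fine, r = ifelse(t_fine >= 2 & t_fine < 10, 30, 0))
  q <- simulate_tissue_tdc(aif, irf, dt_out_s = 1)
  est <- deconvolve_jwl(q, aif)
  jw <- attr(est, "jwl")
  expect_lt(jw$E / jw$k, 0.1 * jw$W)        # tail contribution ~ 0
  expect_equal(est$MTT, 8, tolerance = 0.1) # boxcar width within 10%
})

test_that("all engines: non-negativity and linearity in flow", {
  aif <- fix_aif
  gt <- ground_truth(1, 6, 2)
  q <- simulate_tissue_tdc(aif, make_gamma_variate_irf(gt), dt_out_s = 1)
  set.seed(5)
  qn <- add_noise(q, 1.5)
  q2 <- time_curve(q$t, 2 * q$v)
  mi1 <- deconvolve_fourier(q, aif)$est; mi2 <- deconvolve_fourier(q2, aif)$est
  md1 <- deconvolve_plugflow(q, aif);    md2 <- deconvolve_plugflow(q2, aif)
  jw1 <- deconvolve_jwl(q, aif);         jw2 <- deconvolve_jwl(q2, aif)
  for (e in list(mi1, md1, jw1, deconvolve_fourier(qn, aif)$est,
                 deconvolve_plugflow(qn, aif), deconvolve_jwl(qn, aif))) {
    expect_gte(e$CBF, 0); expect_gte(e$CBV, 0)
  }
  expect_equal(mi2$CBF, 2 * mi1$CBF, tolerance = 1e-9)
  expect_equal(md2$CBF, 2 * md1$CBF, tolerance = 1e-9)
  expect_equal(jw2$CBF, 2 * jw1$CBF, tolerance = 1e-9)
})
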