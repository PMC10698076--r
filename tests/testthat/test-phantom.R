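test_that("time_curve validates its invariants", {
  expect_error(time_curve(1:3, 1:2), "equal length")
  expect_error(time_curve(1, 1), "at least 2")
  expect_error(time_curve(c(0, 0, 1), c(1, 2, 3)), "strictly increasing")
  tc <- time_curve(c(0, 1, 2), c(0, 5, 0))
  expect_identical(curve_area(tc), 5)
})

test_that("arterial curve: baseline, peak range, amplitude linearity", {
  aif <- fix_aif
  expect_true(all(aif$v[aif$t < 9] == 0))
  expect_gt(max(aif$v), 100)
  expect_lt(max(aif$v), 300)
  expect_error(make_arterial_tdc(duration_s = 10), "duration")
  expect_error(make_arterial_tdc(dt_s = 0), "dt_s")

  # recirculation off: pure gamma variate, decays back near baseline late
  pure <- make_arterial_tdc(duration_s = 90, recirc_weight = 0)
  expect_lt(pure$v[length(pure$v)], 0.02 * max(pure$v))

  # area scales linearly with the amplitude parameter
  a1 <- make_arterial_tdc(peak_hu = 100)
  a2 <- make_arterial_tdc(peak_hu = 200)
  expect_equal(curve_area(a2), 2 * curve_area(a1), tolerance = 1e-12)
})

test_that("gamma-variate IRF satisfies its three constraints within 0.1%", {
  cases <- list(c(0, 3.4, 5), c(8, 16, 0.5), c(2, 8, 2.5), c(0.5, 10, 1))
  for (p in cases) {
    gt <- ground_truth(p[1], p[2], p[3])
    irf <- make_gamma_variate_irf(gt)
    expect_equal(max(irf$r), gt$CBF, tolerance = 1e-3)
    expect_equal(trapz_oracle(irf$t, irf$r) / 60, gt$CBV, tolerance = 1e-3)
    expect_lt(abs(irf$t[which.max(irf$r)] - (gt$T0 + 0.5 * gt$MTT)), 0.011)
    expect_true(all(irf$r[irf$t < gt$T0] == 0))
  }
  # peak height equals CBF for the grid's fastest combo
  irf <- make_gamma_variate_irf(ground_truth(0, 3.4, 5))
  expect_equal(max(irf$r), 88.2, tolerance = 5e-4)
})

test_that("gamma shape exponent matches an independent bisection oracle", {
  # peak/area/mode constraints + Central Volume force
  # a * a^a e^-a / Gamma(a+1) = 1/2 for every combo
  f <- function(a) a * exp(a * log(a) - a - lgamma(a + 1)) - 0.5
  a_oracle <- bisect_root(f, 1, 3)
  irf1 <- make_gamma_variate_irf(ground_truth(0, 3.4, 5))
  irf2 <- make_gamma_variate_irf(ground_truth(8, 16, 0.5))
  expect_equal(irf1$a, a_oracle, tolerance = 1e-9)
  expect_identical(irf1$a, irf2$a)
})

test_that("tissue simulation: delta identity, peak bound, area identity", {
  aif <- fix_aif
  # near-delta IRF with unit CBV: Q ~= 0.01 * aif (delayed by the spike time)
  dt <- 0.01
  t_irf <- seq(0, 1, by = dt)
  r <- numeric(length(t_irf))
  r[t_irf == 0.5] <- 60 / dt  # interior spike, trapezoid area 60 -> CBV 1
  q <- simulate_tissue_tdc(aif, list(t = t_irf, r = r))
  ref <- 0.01 * stats::approx(aif$t, aif$v, xout = q$t - 0.5,
                              yleft = 0, yright = 0)$y
  expect_lt(max(abs(q$v - ref)), 0.015 * max(ref))

  # smooth IRF: peak bounded by CBV/100 * aif peak, area ratio = CBV/100
  gt <- ground_truth(1, 4, 3)
  irf <- make_gamma_variate_irf(gt)
  tdc <- simulate_tissue_tdc(aif, irf, duration_s = 60)
  expect_lte(max(tdc$v), gt$CBV / 100 * max(aif$v) * 1.0001)
  long_aif <- make_arterial_tdc(duration_s = 120, recirc_weight = 0)
  long <- simulate_tissue_tdc(long_aif, make_gamma_variate_irf(gt), duration_s = 120)
  expect_equal(curve_area(long) / curve_area(long_aif), gt$CBV / 100,
               tolerance = 0.01)
  expect_error(simulate_tissue_tdc(aif, irf, duration_s = 100), "duration")
})

test_that("noise: sigma-0 identity, calibrated SD, seeded determinism", {
  tdc <- time_curve(seq(0, 60, 2), rep(5, 31))
  expect_identical(add_noise(tdc, 0)$v, tdc$v)
  expect_error(add_noise(tdc, -1), "sigma")

  big <- time_curve(seq_len(1000), rep(0, 1000))
  set.seed(42)
  noise <- add_noise(big, 1.5, n = 100)   # 1e5 samples
  expect_gte(stats::sd(noise), 1.47)
  expect_lte(stats::sd(noise), 1.53)

  set.seed(7); n1 <- add_noise(tdc, 1.5)
  set.seed(7); n2 <- add_noise(tdc, 1.5)
  expect_identical(n1$v, n2$v)
})

test_that("build_phantom: grid structure, reproducibility, mean convergence", {
  cfg <- phantom_config(T0_grid = c(0, 2), MTT_grid = c(4, 8), CBV_grid = c(1, 3),
                        n_real = 1024L)
  ph <- build_phantom(cfg, seed = 11L)
  expect_equal(nrow(ph$combos), 8L)
  expect_equal(ph$combos$CBF, 60 * ph$combos$CBV / ph$combos$MTT)
  expect_equal(ph$combos$Tmax, ph$combos$T0 + 0.5 * ph$combos$MTT)
  expect_true(all(vapply(ph$curves, ncol, integer(1)) == 1024L))
  expect_true(all(vapply(ph$curves, nrow, integer(1)) == length(ph$t)))

  # bit-reproducible under a fixed seed
  ph2 <- build_phantom(cfg, seed = 11L)
  expect_identical(ph$curves, ph2$curves)

  # mean of realizations converges to the clean curve (law of large numbers)
  bound <- 4 * cfg$sigma_hu / sqrt(cfg$n_real)
  for (i in c(1L, 8L)) {
    expect_lt(max(abs(rowMeans(ph$curves[[i]]) - ph$clean[, i])), bound)
  }
})

test_that("phantom_to_table flattens with ground-truth annotation", {
  cfg <- phantom_config(T0_grid = 0, MTT_grid = 4, CBV_grid = c(1, 2),
                        n_real = 3L)
  ph <- build_phantom(cfg, seed = 1L)
  tab <- phantom_to_table(ph)
  expect_equal(nrow(tab), 2 * 3 * length(ph$t))
  expect_setequal(unique(tab$CBV), c(1, 2))
  expect_equal(tab$hu[tab$CBV == 1 & tab$real == 2], ph$curves[[1]][, 2])
})
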