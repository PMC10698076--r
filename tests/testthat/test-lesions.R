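make_test_volume <- function(nx = 16, ny = 16, nz = 2, nt = 8, value = 50) {
  dynamic_volume(array(value, dim = c(nx, ny, nz, nt)),
                 spacing = c(1, 1, 5), times = seq(0, by = 2, length.out = nt),
                 brain_mask = array(TRUE, dim = c(nx, ny, nz)))
}

test_that("smooth_dynamic: identity cases and mask preservation", {
  vol <- make_test_volume()
  expect_identical(smooth_dynamic(vol, 0)$data, vol$data)
  # constant image unchanged (reflection padding keeps edges exact)
  sm <- smooth_dynamic(vol, 2.4)
  expect_equal(sm$data, vol$data, tolerance = 1e-12)
  # out-of-mask voxels untouched
  vol2 <- make_test_volume()
  vol2$brain_mask[1:4, , ] <- FALSE
  set.seed(1)
  vol2$data[] <- stats::rnorm(length(vol2$data), 50, 10)
  sm2 <- smooth_dynamic(vol2, 2.4)
  expect_identical(sm2$data[1:4, , , ], vol2$data[1:4, , , ])
  expect_false(identical(sm2$data[8, 8, 1, 1], vol2$data[8, 8, 1, 1]))
})

test_that("smooth_dynamic: white-noise SD shrinks by the 2D Gaussian gain", {
  set.seed(21)
  n <- 128
  vol <- dynamic_volume(array(stats::rnorm(n * n, 0, 10), dim = c(n, n, 1, 2)),
                        spacing = c(1, 1, 5), times = c(0, 2),
                        brain_mask = array(TRUE, dim = c(n, n, 1)))
  sm <- smooth_dynamic(vol, 2.4)
  inner <- sm$data[20:(n - 20), 20:(n - 20), 1, 1]
  gain <- 1 / (2 * 2.4 * sqrt(pi))   # continuous 2D Gaussian noise gain
  expect_equal(stats::sd(inner), 10 * gain, tolerance = 0.1)
})

test_that("postprocess_mask: closing fills holes, removes speckle", {
  sp <- c(1, 1, 5)
  empty <- array(FALSE, dim = c(20, 20, 1))
  expect_identical(postprocess_mask(empty, sp), empty)

  # solid disk with an interior hole smaller than the element -> hole removed
  m <- matrix(FALSE, 20, 20)
  for (x in 1:20) for (y in 1:20) m[x, y] <- (x - 10)^2 + (y - 10)^2 <= 36
  holed <- m; holed[10, 10] <- FALSE
  closed <- postprocess_mask(array(holed, dim = c(20, 20, 1)), sp)[, , 1]
  expect_true(closed[10, 10])

  # closing is extensive: the input mask is always preserved
  expect_true(all(closed[m]))
  spk <- matrix(FALSE, 20, 20); spk[5, 5] <- TRUE
  out <- postprocess_mask(array(spk, dim = c(20, 20, 1)), sp)[, , 1]
  expect_true(all(out[spk]))
})

test_that("segment_lesions: thresholds, reference CBF, mismatch rules", {
  # construct maps directly: 10x10x1, spacing 10x10x10 mm -> 1 ml per voxel
  dims <- c(10, 10, 1)
  tmax <- array(2, dim = dims); cbf <- array(50, dim = dims)
  tmax[1:5, 1:8, 1] <- 8      # 40 voxels hypoperfused (Tmax > 4 and > 6)
  cbf[1:5, 1:3, 1] <- 5       # 15 voxels low flow -> core
  maps <- structure(list(cbf = cbf, cbv = cbf / 25, mtt = cbf * 0 + 4,
                         tmax = tmax, spacing = c(10, 10, 10),
                         brain_mask = array(TRUE, dim = dims)),
                    class = "parameter_maps")
  rep <- segment_lesions(maps, rcbf_thresh = 0.30, morphology = FALSE)
  expect_equal(rep$ref_cbf, 50)                  # mean CBF over normal tissue
  expect_equal(rep$core_ml, 15)
  expect_equal(rep$penumbra_ml, 40)
  expect_equal(rep$mismatch_ratio, 40 / 15)
  expect_true(rep$favourable)
  # subset invariants pre-morphology
  expect_true(all(rep$core_mask <= rep$hypoperfusion_mask))
  expect_true(all(rep$penumbra_mask <= rep$hypoperfusion_mask))

  # raising rcbf threshold never decreases core volume
  vols <- vapply(c(0.1, 0.3, 0.5, 0.8), function(r) {
    segment_lesions(maps, rcbf_thresh = r, morphology = FALSE)$core_ml
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))

  # empty core -> Inf ratio flag, not an error
  rep0 <- segment_lesions(maps, rcbf_thresh = 0.01, morphology = FALSE)
  expect_identical(rep0$mismatch_ratio, Inf)   # surfaced, never divided
  expect_true(rep0$favourable)                 # empty core is maximally favourable
  expect_true(mismatch_profile(0, 40)$favourable)

  # degenerate: everything hypoperfused
  allhypo <- maps; allhypo$tmax[] <- 9
  expect_error(segment_lesions(allhypo, morphology = FALSE), "degenerate")
})

test_that("mismatch profile verdicts match the published case reports", {
  # favourable: core 26.6 ml, penumbra 68.8 ml -> ratio 2.6
  p1 <- mismatch_profile(26.6, 68.8)
  expect_equal(round(p1$mismatch_ratio, 1), 2.6)
  expect_true(p1$favourable)
  # unfavourable by ratio: core 37.3, penumbra 62.3 -> 1.7 < 1.8
  p2 <- mismatch_profile(37.3, 62.3)
  expect_equal(round(p2$mismatch_ratio, 1), 1.7)
  expect_false(p2$favourable)
  # unfavourable: core 25.8, penumbra 35.2 -> 1.4
  p3 <- mismatch_profile(25.8, 35.2)
  expect_equal(round(p3$mismatch_ratio, 1), 1.4)
  expect_false(p3$favourable)
})

test_that("compute_maps: single-voxel consistency with curve-level engines", {
  study <- make_synthetic_study(synth_config(nx = 24, ny = 24, nz = 1, nt = 25,
                                             lesion_center = c(9, 15),
                                             lesion_radius_core = 3,
                                             lesion_radius_penumbra = 5),
                                seed = 4L)
  vol <- study$volume
  # restrict the mask to the AIF cluster voxel + one tissue voxel
  keep <- array(FALSE, dim = dim(vol$brain_mask))
  av <- vol$aif_voxel
  tv <- c(12, 7, 1)   # a normal-region voxel
  expect_true(study$truth$normal[tv[1], tv[2], tv[3]])
  keep[av[1], av[2], av[3]] <- TRUE
  keep[tv[1], tv[2], tv[3]] <- TRUE
  vol$brain_mask <- keep
  maps <- compute_maps(vol, "md")
  # curve-level reference: same baseline subtraction, same engine
  aif_raw <- vol$data[av[1], av[2], av[3], ]
  q_raw <- vol$data[tv[1], tv[2], tv[3], ]
  arrive <- which(aif_raw - aif_raw[1] > 0.1 * max(aif_raw - aif_raw[1]))[1]
  bl <- seq_len(arrive - 1)
  ca <- time_curve(vol$times, pmax(aif_raw - mean(aif_raw[bl]), 0))
  q <- time_curve(vol$times, q_raw - mean(q_raw[bl]))
  ref <- deconvolve_plugflow(q, ca)
  expect_equal(maps$cbf[tv[1], tv[2], tv[3]], ref$CBF, tolerance = 1e-9)
  expect_equal(maps$tmax[tv[1], tv[2], tv[3]], ref$Tmax, tolerance = 1e-9)
  expect_true(is.na(maps$cbf[1, 1, 1]))
  # md maps satisfy the Central Volume Principle voxel-wise
  ok <- !is.na(maps$cbf)
  expect_equal(maps$cbv[ok], maps$cbf[ok] * maps$mtt[ok] / 60, tolerance = 1e-9)
})

test_that("compute_maps: lesion region has higher Tmax than normal region", {
  study <- make_synthetic_study(synth_config(nx = 32, ny = 32, nz = 1, nt = 25,
                                             lesion_center = c(12, 20),
                                             lesion_radius_core = 4,
                                             lesion_radius_penumbra = 7),
                                seed = 9L)
  vol <- smooth_dynamic(study$volume)
  maps <- compute_maps(vol, "mi")
  les <- study$truth$core | study$truth$penumbra
  expect_gt(stats::median(maps$tmax[les], na.rm = TRUE),
            stats::median(maps$tmax[study$truth$normal], na.rm = TRUE))
  expect_error(compute_maps(vol, "nope"))
})
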