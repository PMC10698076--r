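# 4D dynamic volume -> parameter maps -> lesion masks and mismatch profile.

#' Dynamic 4D volume
#'
#' Container for a dynamic CTP acquisition: a 4D array (x, y, z, t) in HU,
#' voxel spacing (mm), frame times (s), a parenchymal brain mask and the
#' user-supplied arterial (and optionally venous) voxel coordinates.
#'
#' @param data 4D numeric array. @param spacing Numeric length-3, mm/voxel.
#' @param times Frame times, s, strictly increasing.
#' @param brain_mask 3D logical array matching the spatial dims; `NULL`
#'   derives a simple 0-100 HU mask from the temporal-average image.
#' @param aif_voxel Integer (x, y, z) of the arterial voxel.
#' @param vof_voxel Optional venous voxel (unused by the engines, carried).
#' @return A `dynamic_volume` list.
#' @export
dynamic_volume <- function(data, spacing, times, brain_mask = NULL,
                           aif_voxel = NULL, vof_voxel = NULL) {
  d <- dim(data)
  if (length(d) != 4L) stop("dynamic_volume: data must be 4D (x, y, z, t)", call. = FALSE)
  if (length(times) != d[4]) stop("dynamic_volume: times must match 4th dim", call. = FALSE)
  if (any(diff(times) <= 0)) stop("dynamic_volume: times must be strictly increasing", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("dynamic_volume: spacing must be 3 positive mm values", call. = FALSE)
  }
  if (is.null(brain_mask)) {
    # soft-tissue band wide enough to keep contrast-enhanced vessels
    avg <- apply(data, c(1, 2, 3), mean)
    brain_mask <- avg > 5 & avg < 200
  }
  if (!identical(dim(brain_mask), d[1:3])) {
    stop("dynamic_volume: brain_mask shape must match spatial dims", call. = FALSE)
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 times = as.numeric(times),
                 brain_mask = brain_mask, aif_voxel = aif_voxel,
                 vof_voxel = vof_voxel),
            class = "dynamic_volume")
}

#' @export
print.dynamic_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_volume> %dx%dx%d x %d frames, spacing %g x %g x %g mm, %d brain voxels\n",
              d[1], d[2], d[3], d[4], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$brain_mask)))
  invisible(x)
}

# 1D Gaussian kernel truncated at 4 sigma (in voxel units).
gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable 2D Gaussian smoothing of a matrix with reflection padding.
smooth_slice <- function(m, sigma_vox_x, sigma_vox_y) {
  conv1 <- function(v, k) {
    r <- (length(k) - 1L) / 2L
    n <- length(v)
    pad <- c(v[pmin(r:1, n)], v, v[pmax(n - (1:r) + 1L, 1L)])
    out <- stats::filter(pad, k, sides = 2)
    as.numeric(out[(r + 1L):(r + n)])
  }
  kx <- gauss_kernel(sigma_vox_x)
  ky <- gauss_kernel(sigma_vox_y)
  m2 <- apply(m, 2, conv1, k = kx)           # along x (rows)
  t(apply(m2, 1, conv1, k = ky))             # along y (cols)
}

#' Smooth a dynamic volume
#'
#' Per-slice, per-frame 2D Gaussian smoothing of the dynamic images, the
#' standard pre-filter before deconvolution. The kernel standard deviation is
#' given in mm and converted to voxels per in-plane axis. Voxels outside the
#' brain mask are restored to their original values after filtering.
#'
#' @param vol A [dynamic_volume()]. @param sigma_mm Kernel SD, mm
#'   (default 2.4); 0 returns the input unchanged.
#' @return A smoothed [dynamic_volume()].
#' @export
smooth_dynamic <- function(vol, sigma_mm = 2.4) {
  stopifnot(inherits(vol, "dynamic_volume"))
  if (sigma_mm < 0) stop("smooth_dynamic: sigma_mm must be >= 0", call. = FALSE)
  if (sigma_mm == 0) return(vol)
  sx <- sigma_mm / vol$spacing[1]
  sy <- sigma_mm / vol$spacing[2]
  d <- dim(vol$data)
  out <- vol$data
  for (z in seq_len(d[3])) {
    for (f in seq_len(d[4])) {
      out[, , z, f] <- smooth_slice(vol$data[, , z, f], sx, sy)
    }
  }
  keep <- !vol$brain_mask
  if (any(keep)) {
    for (f in seq_len(d[4])) {
      frame <- out[, , , f, drop = FALSE]
      dim(frame) <- d[1:3]
      orig <- vol$data[, , , f, drop = FALSE]
      dim(orig) <- d[1:3]
      frame[keep] <- orig[keep]
      out[, , , f] <- frame
    }
  }
  vol$data <- out
  vol
}

# Bolus arrival frame from the AIF: first time the AIF (baseline-subtracted
# by its first sample) crosses 10% of its peak. Frames strictly before it are
# baseline; at least one baseline frame is kept.
baseline_frames <- function(aif_v, times) {
  v <- aif_v - aif_v[1]
  thr <- 0.10 * max(v)
  arrival <- which(v > thr)[1]
  if (is.na(arrival) || arrival < 2L) arrival <- 2L
  seq_len(arrival - 1L)
}

#' Compute perfusion parameter maps
#'
#' Voxel-wise deconvolution of the arterial TDC from every in-mask tissue
#' TDC. All curves are baseline-subtracted (mean over the pre-bolus frames,
#' found by the 10\%-of-peak AIF arrival crossing) before deconvolution.
#' Out-of-mask voxels carry `NA`.
#'
#' @param vol A [dynamic_volume()] (already smoothed if desired).
#' @param engine `"mi"`, `"md"` or `"jwl"`.
#' @param reg_frac Regularization fraction for `"mi"`.
#' @param grid Search grid for the model-based engines.
#' @param chunk Voxels deconvolved per matrix batch.
#' @return A `parameter_maps` list: 3D arrays `cbf` (ml/min/100 g), `cbv`
#'   (ml/100 g), `mtt` (s), `tmax` (s), plus `spacing` and `brain_mask`.
#' @export
compute_maps <- function(vol, engine = c("mi", "md", "jwl"),
                         reg_frac = 0.2, grid = NULL, chunk = 4096L) {
  stopifnot(inherits(vol, "dynamic_volume"))
  engine <- match.arg(engine)
  if (is.null(vol$aif_voxel)) stop("compute_maps: aif_voxel required", call. = FALSE)
  av <- vol$aif_voxel
  if (!vol$brain_mask[av[1], av[2], av[3]]) {
    stop("compute_maps: aif_voxel must lie inside the brain mask", call. = FALSE)
  }
  d <- dim(vol$data)
  aif_raw <- vol$data[av[1], av[2], av[3], ]
  bl <- baseline_frames(aif_raw, vol$times)
  ca_v <- aif_raw - mean(aif_raw[bl])
  ca_tc <- time_curve(vol$times, pmax(ca_v, 0))

  t_raw <- vol$times
  t_grid <- seq(0, floor(t_raw[length(t_raw)] - t_raw[1]), by = 1)
  Wm <- interp_matrix(t_raw - t_raw[1], t_grid)
  ca_shift <- time_curve(t_raw - t_raw[1], ca_tc$v)
  ca <- interp_curve(ca_shift, t_grid)
  area_ca <- trapz(t_raw, ca_tc$v)
  if (area_ca <= 0) stop("compute_maps: arterial curve has non-positive area", call. = FALSE)

  design <- switch(engine,
    mi = NULL,
    md = plugflow_design(ca_shift, t_grid, if (is.null(grid)) plugflow_grid() else grid),
    jwl = jwl_design(ca_shift, t_grid, if (is.null(grid)) jwl_grid() else grid)
  )

  idx <- which(vol$brain_mask)
  nvox <- length(idx)
  n_spatial <- prod(d[1:3])
  flat <- matrix(vol$data, nrow = n_spatial, ncol = d[4])
  maps <- list(cbf = rep(NA_real_, n_spatial), cbv = rep(NA_real_, n_spatial),
               mtt = rep(NA_real_, n_spatial), tmax = rep(NA_real_, n_spatial))
  for (start in seq(1L, nvox, by = chunk)) {
    sel <- idx[start:min(start + chunk - 1L, nvox)]
    qraw <- t(flat[sel, , drop = FALSE])               # nt x nvox
    qraw <- qraw - rep(colMeans(qraw[bl, , drop = FALSE]), each = d[4])
    qmat <- Wm %*% qraw
    if (engine == "mi") {
      core <- fourier_core(qmat, ca, t_grid, reg_frac)
      w <- diff(t_raw)
      area_q <- colSums((qraw[-1, , drop = FALSE] + qraw[-d[4], , drop = FALSE]) / 2 * w)
      cbf <- core$cbf
      cbv <- pmax(100 * area_q / area_ca, 0)
      mtt <- ifelse(cbf > 0, 60 * cbv / cbf, Inf)
      tmax <- core$tmax
    } else if (engine == "md") {
      fit <- plugflow_core(qmat, design)
      cbf <- FLOW_UNIT_SCALE * fit$F
      mtt <- fit$MTT
      cbv <- cbf * mtt / 60
      tmax <- fit$T0 + 0.5 * mtt
    } else {
      fit <- jwl_core(qmat, design)
      cbf <- FLOW_UNIT_SCALE * fit$F
      mtt <- fit$W + fit$E / fit$k
      cbv <- cbf * mtt / 60
      tmax <- fit$T0 + 0.5 * mtt
    }
    maps$cbf[sel] <- cbf; maps$cbv[sel] <- cbv
    maps$mtt[sel] <- mtt; maps$tmax[sel] <- tmax
  }
  out <- lapply(maps, function(v) array(v, dim = d[1:3]))
  structure(c(out, list(spacing = vol$spacing, brain_mask = vol$brain_mask,
                        engine = engine)),
            class = "parameter_maps")
}

## ---------------------------------------------------------------------------
## Morphology

# Offsets of a 2D disk structuring element of the given radius (mm) on the
# in-plane voxel lattice.
disk_offsets <- function(radius_mm, spacing) {
  rx <- floor(radius_mm / spacing[1])
  ry <- floor(radius_mm / spacing[2])
  off <- expand.grid(dx = -rx:rx, dy = -ry:ry)
  keep <- (off$dx * spacing[1])^2 + (off$dy * spacing[2])^2 <= radius_mm^2
  off[keep, , drop = FALSE]
}

shift_mat <- function(m, dx, dy, fill = FALSE) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(fill, n1, n2)
  xs <- seq_len(n1) - dx
  ys <- seq_len(n2) - dy
  okx <- xs >= 1 & xs <= n1
  oky <- ys >= 1 & ys <= n2
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

dilate_slice <- function(m, off) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_mat(m, off$dx[i], off$dy[i], fill = FALSE)
  }
  out
}

erode_slice <- function(m, off) {
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_mat(m, off$dx[i], off$dy[i], fill = FALSE)
  }
  out
}

# Fill holes: background connected to the slice border (4-connectivity) stays
# background; enclosed background becomes foreground.
fill_holes_slice <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  reach <- matrix(FALSE, n1, n2)
  bg <- !m
  border <- which(bg & (row(m) == 1 | row(m) == n1 | col(m) == 1 | col(m) == n2))
  if (!length(border)) return(m | bg)  # no border background: everything enclosed
  queue <- border
  reach[queue] <- TRUE
  while (length(queue)) {
    cur <- queue
    queue <- integer(0)
    for (delta in c(-1L, 1L, -n1, n1)) {
      nb <- cur + delta
      ok <- nb >= 1L & nb <= n1 * n2
      # prevent row wrap for left/right moves
      if (delta == -1L) ok <- ok & (cur - 1L) %% n1 != 0L
      if (delta == 1L) ok <- ok & cur %% n1 != 0L
      nb <- nb[ok]
      nb <- nb[bg[nb] & !reach[nb]]
      if (length(nb)) {
        reach[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    queue <- unique(queue)
  }
  m | (bg & !reach)
}

#' Morphological post-processing of a lesion mask
#'
#' Dilation, hole filling, then erosion with a disk structuring element
#' (default 5 mm diameter), applied independently to each axial slice --
#' a morphological closing that removes speckle holes and smooths lesion
#' boundaries against map noise.
#'
#' @param mask 3D (or 2D) logical array. @param spacing mm per axis.
#' @param radius_mm Disk radius, mm (default 2.5, i.e. a 5 mm disk).
#' @return The post-processed logical mask, same shape.
#' @export
postprocess_mask <- function(mask, spacing, radius_mm = 2.5) {
  two_d <- length(dim(mask)) == 2L || is.null(dim(mask))
  if (two_d) mask <- array(mask, dim = c(dim(as.matrix(mask)), 1L))
  off <- disk_offsets(radius_mm, spacing)
  out <- mask
  for (z in seq_len(dim(mask)[3])) {
    m <- mask[, , z]
    m <- dilate_slice(m, off)
    m <- fill_holes_slice(m)
    m <- erode_slice(m, off)
    out[, , z] <- m
  }
  if (two_d) out <- out[, , 1L]
  out
}

## ---------------------------------------------------------------------------
## Segmentation and mismatch profile

#' Segment stroke lesions and evaluate the mismatch profile
#'
#' Applies the threshold rules to parameter maps: hypoperfused tissue is
#' parenchymal brain with Tmax > `hypo_thresh` (default 4 s) and normal
#' tissue its complement; the mean CBF of normal tissue is the reference for
#' relative CBF; ischemic core is relative CBF < `rcbf_thresh` within the
#' hypoperfusion mask; penumbra is Tmax > `tmax_thresh` (default 6 s) within
#' the hypoperfusion mask. Each mask is then morphologically post-processed
#' ([postprocess_mask()]). Volumes are voxel counts times voxel volume (ml);
#' the mismatch ratio is penumbra/core, and the target mismatch profile is
#' favourable iff core < 70 ml, penumbra >= 15 ml and ratio >= 1.8.
#'
#' @param maps A `parameter_maps` from [compute_maps()].
#' @param rcbf_thresh Relative CBF core threshold, fraction (e.g. 0.30
#'   reference, 0.15 calibrated model-based).
#' @param tmax_thresh Penumbra Tmax threshold, s.
#' @param hypo_thresh Hypoperfusion Tmax threshold, s.
#' @param morphology Apply morphological post-processing (default TRUE).
#' @param radius_mm Disk radius for [postprocess_mask()].
#' @return A `lesion_report` list: the three masks, `core_ml`,
#'   `penumbra_ml`, `mismatch_ratio` (Inf flag when core is empty),
#'   `favourable` plus per-criterion booleans, and the reference CBF.
#' @export
segment_lesions <- function(maps, rcbf_thresh = 0.30, tmax_thresh = 6.0,
                            hypo_thresh = 4.0, morphology = TRUE,
                            radius_mm = 2.5) {
  stopifnot(inherits(maps, "parameter_maps"))
  brain <- maps$brain_mask
  tmax <- maps$tmax
  cbf <- maps$cbf
  hypo <- brain & !is.na(tmax) & tmax > hypo_thresh
  normal <- brain & !is.na(tmax) & tmax <= hypo_thresh
  if (!any(normal)) stop("segment_lesions: no normally perfused tissue (degenerate reference)", call. = FALSE)
  ref_cbf <- mean(cbf[normal])
  core <- hypo & cbf < rcbf_thresh * ref_cbf
  penumbra <- hypo & tmax > tmax_thresh
  if (morphology) {
    hypo <- postprocess_mask(hypo, maps$spacing, radius_mm)
    core <- postprocess_mask(core, maps$spacing, radius_mm)
    penumbra <- postprocess_mask(penumbra, maps$spacing, radius_mm)
  }
  vox_ml <- prod(maps$spacing) / 1000
  core_ml <- sum(core) * vox_ml
  pen_ml <- sum(penumbra) * vox_ml
  ratio <- if (core_ml > 0) pen_ml / core_ml else Inf
  crit <- list(core_lt_70 = core_ml < 70,
               penumbra_ge_15 = pen_ml >= 15,
               ratio_ge_1.8 = ratio >= 1.8)
  structure(list(
    hypoperfusion_mask = hypo, core_mask = core, penumbra_mask = penumbra,
    core_ml = core_ml, penumbra_ml = pen_ml, mismatch_ratio = ratio,
    favourable = all(unlist(crit)), criteria = crit,
    ref_cbf = ref_cbf,
    thresholds = list(rcbf = rcbf_thresh, tmax = tmax_thresh, hypo = hypo_thresh)
  ), class = "lesion_report")
}

#' Mismatch profile from lesion volumes
#'
#' Evaluates the target-mismatch rule on already-measured volumes (useful for
#' tabulated data): favourable iff core < 70 ml, penumbra >= 15 ml and
#' mismatch ratio >= 1.8.
#'
#' @param core_ml Core volume, ml. @param penumbra_ml Penumbra volume, ml.
#' @return List with `mismatch_ratio` and `favourable` plus the per-criterion
#'   booleans.
#' @export
mismatch_profile <- function(core_ml, penumbra_ml) {
  ratio <- if (core_ml > 0) penumbra_ml / core_ml else Inf
  crit <- list(core_lt_70 = core_ml < 70,
               penumbra_ge_15 = penumbra_ml >= 15,
               ratio_ge_1.8 = ratio >= 1.8)
  list(mismatch_ratio = ratio, favourable = all(unlist(crit)), criteria = crit)
}

#' @export
print.lesion_report <- function(x, ...) {
  cat(sprintf(
    "<lesion_report> core %.1f ml, penumbra %.1f ml, mismatch ratio %s -> %s\n",
    x$core_ml, x$penumbra_ml,
    if (is.finite(x$mismatch_ratio)) sprintf("%.1f", x$mismatch_ratio) else "Inf (no core)",
    if (x$favourable) "favourable" else "unfavourable"
  ))
  invisible(x)
}
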