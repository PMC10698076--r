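# Synthetic 4D study generator: a small brain-like dynamic volume with known
# ground-truth regions, used to exercise the full pipeline without patient
# data.

#' Synthetic study configuration
#'
#' Geometry and physiology of the synthetic 4D fixture: an elliptical "brain"
#' of normal tissue containing a circular lesion made of a core surrounded by
#' a penumbra ring, an arterial voxel cluster carrying the arterial curve,
#' and background air. Region physiology defaults are chosen far from the
#' mismatch criterion boundaries: normal tissue (CBV 3 ml/100 g, MTT 3.4 s,
#' T0 0.3 s -> CBF 52.9, Tmax 2.0 s), penumbra (CBV 2, MTT 8, T0 4 -> CBF
#' 15, Tmax 8 s), core (CBV 0.8, MTT 16, T0 8 -> CBF 3, Tmax 16 s).
#'
#' @param nx,ny,nz,nt Volume shape (default 64 x 64 x 4 x 30 frames).
#' @param dt_s Frame interval, s (default 2).
#' @param spacing mm per voxel.
#' @param sigma_hu Tissue noise SD, HU.
#' @param baseline_hu Pre-contrast tissue attenuation, HU.
#' @param lesion_center,lesion_radius_core,lesion_radius_penumbra In-plane
#'   lesion geometry, voxels.
#' @param normal,penumbra,core Lists of (T0, MTT, CBV) per region.
#' @param aif Arterial [time_curve()] (default [make_arterial_tdc()]).
#' @return A `synth_config` list.
#' @export
synth_config <- function(nx = 64, ny = 64, nz = 4, nt = 30, dt_s = 2,
                         spacing = c(1.8, 1.8, 5),
                         sigma_hu = 1.5, baseline_hu = 35,
                         lesion_center = c(22, 40),
                         lesion_radius_core = 7,
                         lesion_radius_penumbra = 13,
                         normal = list(T0 = 0.3, MTT = 3.4, CBV = 3),
                         penumbra = list(T0 = 4, MTT = 8, CBV = 2),
                         core = list(T0 = 8, MTT = 16, CBV = 0.8),
                         aif = NULL) {
  if (is.null(aif)) aif <- make_arterial_tdc(duration_s = (nt - 1) * dt_s)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic 4D dynamic study
#'
#' Builds a brain-like dynamic volume from phantom physics: each tissue
#' region's time-density curve is the convolution of the arterial curve with
#' a gamma-variate flow-scaled IRF at the region's ground-truth parameters
#' ([simulate_tissue_tdc()]), offset by the baseline attenuation, with
#' independent Gaussian noise per voxel. A 2x2 voxel arterial cluster in the
#' first slice carries the (noise-free) arterial curve. Ground-truth masks
#' are returned for end-to-end assertions.
#'
#' @param config A [synth_config()]. @param seed Integer seed.
#' @return List: `volume` (a [dynamic_volume()]), `truth` (list of logical
#'   masks `normal`, `penumbra`, `core`, `hypoperfusion` and the per-region
#'   [ground_truth()] parameters), `config`, `seed`.
#' @export
make_synthetic_study <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  nx <- config$nx; ny <- config$ny; nz <- config$nz; nt <- config$nt
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  rx <- nx * 0.42; ry <- ny * 0.42
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  brain2d <- ((xg - cx) / rx)^2 + ((yg - cy) / ry)^2 <= 1

  lc <- config$lesion_center
  dist2 <- (xg - lc[1])^2 + (yg - lc[2])^2
  core2d <- brain2d & dist2 <= config$lesion_radius_core^2
  pen2d <- brain2d & dist2 <= config$lesion_radius_penumbra^2 & !core2d
  if (!any(core2d) || !any(pen2d)) {
    stop("make_synthetic_study: lesion regions fall outside the volume", call. = FALSE)
  }
  normal2d <- brain2d & !core2d & !pen2d

  rep3d <- function(m) array(rep(m, nz), dim = c(nx, ny, nz))
  masks <- list(normal = rep3d(normal2d), penumbra = rep3d(pen2d),
                core = rep3d(core2d))
  brain <- rep3d(brain2d)

  gts <- lapply(config[c("normal", "penumbra", "core")],
                function(p) ground_truth(p$T0, p$MTT, p$CBV))
  curves <- lapply(gts, function(gt) {
    irf <- make_gamma_variate_irf(gt)
    simulate_tissue_tdc(config$aif, irf, dt_out_s = config$dt_s,
                        duration_s = (nt - 1) * config$dt_s)$v
  })

  set.seed(seed %% .Machine$integer.max)
  data <- array(0, dim = c(nx, ny, nz, nt))
  flat <- matrix(0, nx * ny * nz, nt)
  for (region in names(masks)) {
    idx <- which(masks[[region]])
    n <- length(idx)
    sig <- matrix(rep(curves[[region]] + config$baseline_hu, each = n), n, nt)
    flat[idx, ] <- sig + matrix(stats::rnorm(n * nt, sd = config$sigma_hu), n, nt)
  }
  # arterial cluster: 2x2 in-plane, slice 1, noise-free
  aif_t <- seq(0, (nt - 1) * config$dt_s, by = config$dt_s)
  aif_v <- interp_curve(config$aif, aif_t) + config$baseline_hu
  ax <- round(cx) + c(0L, 1L); ay <- round(cy - ry / 2) + c(0L, 1L)
  if (any(rep3d(dist2 <= config$lesion_radius_penumbra^2)[ax, ay, 1L])) {
    stop("make_synthetic_study: arterial cluster overlaps the lesion", call. = FALSE)
  }
  for (x in ax) for (y in ay) {
    flat[x + (y - 1L) * nx, ] <- aif_v
    brain[x, y, 1L] <- TRUE
  }
  data <- array(flat, dim = c(nx, ny, nz, nt))

  vol <- dynamic_volume(
    data, spacing = config$spacing, times = aif_t, brain_mask = brain,
    aif_voxel = c(ax[1], ay[1], 1L)
  )
  list(
    volume = vol,
    truth = list(
      normal = masks$normal, penumbra = masks$penumbra, core = masks$core,
      hypoperfusion = masks$penumbra | masks$core,
      params = gts
    ),
    config = config, seed = as.integer(seed)
  )
}

#' Dice similarity coefficient
#'
#' Overlap of two binary masks: 2|A & B| / (|A| + |B|).
#'
#' @param a,b Logical arrays of identical shape.
#' @return Dice coefficient in [0, 1] (1 when both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
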