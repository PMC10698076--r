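# Run configuration: JSON round-trip of every tunable setting, with defaults
# matching the published experiment.

#' Default run configuration
#'
#' All tunable settings of the toolkit in one structure, with defaults equal
#' to the published experiment: the phantom grids, sigma = 1.5 HU and 1024
#' realizations; 20\% Fourier regularization; the 575-pair plug-flow grid;
#' reference thresholds relative CBF 30\%, Tmax 6 s, hypoperfusion 4 s;
#' N_GT = 50 ml/min/100 g; 2.4 mm smoothing; 5 mm morphology disk; mismatch
#' criteria 70 ml / 15 ml / 1.8.
#'
#' @return A nested list of settings (class `run_config`).
#' @export
default_run_config <- function() {
  structure(list(
    phantom = list(
      T0_grid = c(0, 0.5, 1, 2, 3, 4, 8),
      MTT_grid = c(3.4, 4, 6, 8, 10, 12, 16),
      CBV_grid = c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5),
      n_real = 1024L, sigma_hu = 1.5,
      duration_s = 60, dt_sim_s = 0.01, dt_out_s = 2
    ),
    engines = list(
      reg_frac = 0.2,
      plugflow = list(T0_values = 0:24, MTT_values = 2:24),
      jwl = list(T0_values = 0:24, W_values = 2:24,
                 k_values = c(0.1, 0.2, 0.4, 0.8, 1.6))
    ),
    calibration = list(R_MI = 0.30, T_MI = 6.0, N_GT = 50, cbv_exclude = 0.5),
    lesions = list(
      smoothing_sigma_mm = 2.4, hypo_thresh_s = 4.0, tmax_thresh_s = 6.0,
      rcbf_reference = 0.30, morphology_radius_mm = 2.5,
      criteria = list(core_ml = 70, penumbra_ml = 15, ratio = 1.8)
    ),
    seed = 1L
  ), class = "run_config")
}

#' Write / read a run configuration
#'
#' JSON round-trip of a [default_run_config()]-shaped list. Numeric vectors
#' and integer flags survive the round trip exactly.
#'
#' @param config A `run_config` list. @param path File path.
#' @return `read_run_config` returns the `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$phantom$n_real <- as.integer(cfg$phantom$n_real)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}
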