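#' Run configuration
#'
#' A run configuration is a plain named list (read from YAML by
#' [read_run_config()]) with blocks `phantom` (arguments of
#' [phantom_spec()], with a nested `injection` block for
#' [injection_model()]), `regions` (region-scheme geometry), optional
#' `kinetics`, plus `output_dir` and `seed`.  It is validated against the
#' known key sets before any computation: unknown keys are rejected with a
#' message naming them.
#'
#' @return `default_run_config` returns the default configuration list:
#'   the standard phantom (1.4 kBq/cc background, 6 mm PSF, 1 mm grid,
#'   15 x 20 s frames), a 20 mm single-segment region scheme with 15 mm
#'   spill-out and 10 mm background-ring margins and a 25 mm combined
#'   artery/vein cylinder, and seed 1.
#' @export
default_run_config <- function() {
  list(
    phantom = list(background_activity_kBq_cc = 1.4,
                   injection = list()),
    regions = list(spill_margin_mm = 15, bkg_margin_mm = 10,
                   combined_radius_mm = 25, roi_length_mm = 20,
                   replicates = 1L, weighting = "fractional"),
    kinetics = list(enabled = FALSE, K1 = 0.1, k2 = 0.1, k3 = 0.03),
    output_dir = NULL,
    seed = 1L)
}

config_allowed <- list(
  top = c("phantom", "regions", "kinetics", "output_dir", "seed"),
  phantom = c("tube_bank", "tube_spacing_mm", "vein_offset_mm",
              "background_activity_kBq_cc", "psf_fwhm_mm", "voxel_size_mm",
              "frame_schedule", "injection", "flow_rate_mL_s",
              "tube_length_mm", "fov_mm", "noise", "tracer_half_life_min",
              "decay"),
  injection = c("injected_activity_MBq", "injection_rate_mL_s",
                "injection_duration_s", "chamber_volume_mL",
                "buffer_volume_mL", "sample_dt_s"),
  regions = c("spill_margin_mm", "bkg_margin_mm", "combined_radius_mm",
              "roi_length_mm", "replicates", "weighting"),
  kinetics = c("enabled", "K1", "k2", "k3"))

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")))
  invisible(x)
}

#' @rdname default_run_config
#' @param config a configuration list.
#' @return `validate_run_config` returns the configuration merged over the
#'   defaults, or errors naming the offending key.
#' @export
validate_run_config <- function(config) {
  check_keys(config, config_allowed$top, "config")
  check_keys(config$phantom, config_allowed$phantom, "config$phantom")
  check_keys(config$phantom$injection, config_allowed$injection,
             "config$phantom$injection")
  check_keys(config$regions, config_allowed$regions, "config$regions")
  check_keys(config$kinetics, config_allowed$kinetics, "config$kinetics")
  def <- default_run_config()
  merged <- utils::modifyList(def, config)
  if (!is.numeric(merged$seed) || length(merged$seed) != 1L)
    stop("config$seed must be a single integer")
  merged$seed <- as.integer(merged$seed)
  merged
}

#' @rdname default_run_config
#' @param path YAML configuration file.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop(sprintf("'%s' is not a YAML mapping", path))
  validate_run_config(cfg)
}
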