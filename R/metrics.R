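#' Area under a time-activity curve
#'
#' Rectangle rule, matching the dynamic-PET convention for framed data:
#' the sum of each frame's mean activity multiplied by its duration, in
#' kBq.s/cc.  (Trapezoidal integration is deliberately not used; frame
#' means already integrate the signal within each frame.)
#'
#' @param x a [tac()].
#' @return AUC in `units * s`.
#' @examples
#' auc(tac(seq(0, 280, 20), 20, rep(5, 15)))  # 1500
#' @export
auc <- function(x) {
  stopifnot_tac(x)
  sum(x$value * x$frame_duration_s)
}

#' Average a finely sampled curve onto a dynamic frame schedule
#'
#' Each output frame is the mean of the fine samples whose bins fall in
#' `[start, start + duration)`.  This reproduces what a dynamic scan does
#' to an instantaneous reference curve, including the peak flattening
#' (temporal aliasing) of transients narrower than the frame duration.
#'
#' @param fine a finely, uniformly sampled [tac()].
#' @param schedule a [tac()] (values ignored) or data frame with
#'   `frame_start_s` and `frame_duration_s` defining the target frames.
#' @return a [tac()] on the target schedule.
#' @export
temporal_average <- function(fine, schedule) {
  stopifnot_tac(fine)
  starts <- schedule$frame_start_s
  durs <- schedule$frame_duration_s
  if (is.null(starts) || is.null(durs))
    stop("schedule needs frame_start_s and frame_duration_s")
  dt <- fine_dt(fine)
  lo <- min(fine$frame_start_s)
  hi <- max(fine$frame_start_s) + dt
  vals <- vapply(seq_along(starts), function(i) {
    a <- starts[i]; b <- starts[i] + durs[i]
    if (a < lo - 1e-9 || b > hi + 1e-9)
      stop(sprintf("fine curve does not cover frame %d [%g, %g)", i, a, b))
    sel <- fine$frame_start_s >= a - 1e-9 & fine$frame_start_s < b - 1e-9
    mean(fine$value[sel])
  }, numeric(1))
  tac(starts, durs, vals, units = tac_units(fine))
}

#' Ground-truth AUC from injected activity and flow
#'
#' In a flow circuit every delivered becquerel passes the tube cross
#' section exactly once, so the true AUC of the input function is the
#' delivered activity (decay-corrected to the experiment reference time)
#' divided by the volumetric flow rate.
#'
#' @param delivered_activity_kBq delivered activity (kBq).
#' @param flow_rate_mL_s volumetric flow (mL/s).
#' @param half_life_min tracer half-life (min); used with
#'   `decay_interval_s`.
#' @param decay_interval_s time from activity assay to the experiment (s);
#'   positive values decay the activity.  Default 0.
#' @return AUC in kBq.s/cc.
#' @examples
#' ground_truth_auc(22000, 10)  # 2200
#' @export
ground_truth_auc <- function(delivered_activity_kBq, flow_rate_mL_s,
                             half_life_min = 109.77, decay_interval_s = 0) {
  if (!is.finite(flow_rate_mL_s) || flow_rate_mL_s <= 0)
    stop("flow rate must be positive")
  if (delivered_activity_kBq < 0) stop("delivered activity must be >= 0")
  delivered_activity_kBq * 2^(-decay_interval_s / (half_life_min * 60)) /
    flow_rate_mL_s
}

#' Decay-correct a time-activity curve
#'
#' Multiplies each frame by `2^((t_mid - reference) / half_life)` with
#' `t_mid` the frame midpoint, i.e. frames after the reference time are
#' scaled up to compensate physical decay.  Correcting by `dt` and then by
#' `-dt` is an exact identity.
#'
#' @param x a [tac()].
#' @param half_life_min half-life in minutes (F-18: 109.77).
#' @param reference_time_s reference time in seconds.
#' @return a [tac()].
#' @export
decay_correct <- function(x, half_life_min = 109.77, reference_time_s = 0) {
  stopifnot_tac(x)
  if (!is.finite(half_life_min) || half_life_min <= 0)
    stop("half_life_min must be positive")
  f <- 2^((tac_midpoints(x) - reference_time_s) / (half_life_min * 60))
  tac(x$frame_start_s, x$frame_duration_s, x$value * f, units = tac_units(x))
}

#' CT-to-PET intensity scaling factor
#'
#' Converts the CT contrast-enhancement calibration (HU per mgI/mL) into
#' an HU-per-kBq/cc factor for overlaying DCE-CT reference curves on PET
#' curves, assuming both agents were injected into the same circuit and
#' share the same dilution volume: `ce * iodine_mass / activity_kBq`.
#'
#' @param contrast_enhancement_HU_per_mgI_mL contrast calibration
#'   (HU per mgI/mL).
#' @param iodine_mass_mg total injected iodine (mg).
#' @param activity_MBq total injected activity (MBq).
#' @return scaling factor in HU per kBq/cc.
#' @examples
#' hu_activity_scaling(23, 4625, 22)  # ~4.8
#' @export
hu_activity_scaling <- function(contrast_enhancement_HU_per_mgI_mL,
                                iodine_mass_mg, activity_MBq) {
  vals <- c(contrast_enhancement_HU_per_mgI_mL, iodine_mass_mg, activity_MBq)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all scaling inputs must be positive")
  contrast_enhancement_HU_per_mgI_mL * iodine_mass_mg / (activity_MBq * 1000)
}

#' Percent error and percent improvement
#'
#' `percent_error` is the signed relative error `100 (measured - truth) /
#' truth`.  `percent_improvement` is the convention used for correction
#' summaries: the drop in absolute percent error, `|err_uncorrected| -
#' |err_corrected|`, in percentage points (not a ratio).
#'
#' @param measured,truth numeric vectors (truth must be nonzero).
#' @return percent values.
#' @export
percent_error <- function(measured, truth) {
  if (any(truth == 0)) stop("truth must be nonzero")
  100 * (measured - truth) / truth
}

#' @rdname percent_error
#' @param err_uncorrected,err_corrected percent errors (signed).
#' @export
percent_improvement <- function(err_uncorrected, err_corrected) {
  abs(err_uncorrected) - abs(err_corrected)
}
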