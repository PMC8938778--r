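#' Injection model for the flow phantom
#'
#' Describes how activity enters the flow circuit: a syringe pump delivers
#' `injected_activity_MBq` at `injection_rate_mL_s` for
#' `injection_duration_s` into a well-mixed chamber of volume
#' `chamber_volume_mL` that is flushed by the circuit flow; the smallest
#' tube feeds a venous buffer compartment of `buffer_volume_mL` that
#' delays and disperses the curve before it re-enters as "venous" flow.
#'
#' @param injected_activity_MBq total activity delivered (MBq); default 22.
#' @param injection_rate_mL_s syringe rate (mL/s); default 0.5.
#' @param injection_duration_s injection duration (s); default 50.
#' @param chamber_volume_mL mixing-chamber volume (mL); default 100.  This
#'   sets the rise/washout time constant `chamber_volume / flow_rate` of
#'   the arterial curve.
#' @param buffer_volume_mL venous dilution volume (mL); default 150.
#' @param sample_dt_s fine sampling step of ground-truth curves (s);
#'   default 0.5, much shorter than any dynamic frame.
#' @return An object of class `injection_model`.
#' @export
injection_model <- function(injected_activity_MBq = 22,
                            injection_rate_mL_s = 0.5,
                            injection_duration_s = 50,
                            chamber_volume_mL = 100,
                            buffer_volume_mL = 150,
                            sample_dt_s = 0.5) {
  vals <- c(injected_activity_MBq, injection_rate_mL_s, injection_duration_s,
            buffer_volume_mL, sample_dt_s)
  if (any(!is.finite(vals)) || any(vals <= 0) ||
      !is.finite(chamber_volume_mL) || chamber_volume_mL < 0)
    stop("non-physical injection parameters")
  structure(list(injected_activity_MBq = injected_activity_MBq,
                 injection_rate_mL_s = injection_rate_mL_s,
                 injection_duration_s = injection_duration_s,
                 chamber_volume_mL = chamber_volume_mL,
                 buffer_volume_mL = buffer_volume_mL,
                 sample_dt_s = sample_dt_s),
            class = "injection_model")
}

default_tube_bank <- function(tube_spacing_mm = 63.5, vein_offset_mm = 20) {
  x <- c(0, 1, 2, 3) * tube_spacing_mm
  data.frame(
    label = c("tube_25.4", "tube_12.7", "tube_9.5", "tube_6.35", "vein_6.35"),
    diameter_mm = c(25.4, 12.7, 9.5, 6.35, 6.35),
    x_mm = c(x, x[4] + vein_offset_mm),
    y_mm = 0,
    role = c("artery", "artery", "artery", "artery", "vein"),
    stringsAsFactors = FALSE)
}

#' Digital flow-phantom specification
#'
#' Full description of the synthetic experiment: a bank of parallel flow
#' tubes (z-aligned cylinders) carrying a common arterial input function —
#' by design every artery tube sees the same curve, so peak and AUC are
#' identical across diameters — plus a companion venous tube carrying the
#' buffered (delayed, dispersed) curve, all inside a uniform background
#' compartment.  Frames are rendered, blurred with an isotropic Gaussian
#' PSF to emulate the scanner resolution, and optionally degraded with
#' frame-duration-dependent noise.
#'
#' @param tube_bank data frame with columns `label`, `diameter_mm`, `x_mm`,
#'   `y_mm`, `role` (`"artery"` or `"vein"`); default: 25.4, 12.7, 9.5 and
#'   6.35 mm arteries spaced `tube_spacing_mm` apart plus a 6.35 mm vein
#'   `vein_offset_mm` from the smallest artery.
#' @param tube_spacing_mm centre-to-centre artery spacing (mm); default
#'   63.5.
#' @param vein_offset_mm vein centre distance from the smallest artery
#'   (mm); default 20.
#' @param background_activity_kBq_cc uniform background concentration
#'   (kBq/cc); default 1.4.  Set 0 for the background-free experiment.
#' @param psf_fwhm_mm isotropic Gaussian PSF FWHM (mm); default 6.
#' @param voxel_size_mm isotropic simulation grid spacing (mm); default 1.
#' @param frame_schedule data frame `start_s`, `duration_s`; default 15
#'   frames of 20 s.
#' @param injection an [injection_model()].
#' @param flow_rate_mL_s circuit flow (mL/s); default 10.
#' @param tube_length_mm length of the rendered tube segment (mm); default
#'   40.
#' @param fov_mm field of view: list with `x`, `y`, `z` length-2 ranges
#'   (mm); default sized to hold the tube bank, its measurement regions and
#'   a margin of at least 3 PSF FWHM.
#' @param noise list `model` (`"none"` or `"gaussian"`), `k`, `floor`; see
#'   [add_noise()].  Default: no noise.
#' @param seed integer seed for the noise model.
#' @param tracer_half_life_min radiotracer half-life (min); default 109.77
#'   (F-18).
#' @param decay `"corrected"` (default: frames are decay-corrected to
#'   injection time, as scanner output would be) or `"physical"` (frames
#'   carry physical decay; undo with [decay_correct()]).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(tube_bank = NULL,
                         tube_spacing_mm = 63.5,
                         vein_offset_mm = 20,
                         background_activity_kBq_cc = 1.4,
                         psf_fwhm_mm = 6,
                         voxel_size_mm = 1,
                         frame_schedule = data.frame(
                           start_s = seq(0, by = 20, length.out = 15),
                           duration_s = 20),
                         injection = injection_model(),
                         flow_rate_mL_s = 10,
                         tube_length_mm = 40,
                         fov_mm = NULL,
                         noise = list(model = "none"),
                         seed = 1L,
                         tracer_half_life_min = 109.77,
                         decay = c("corrected", "physical")) {
  decay <- match.arg(decay)
  if (is.null(tube_bank))
    tube_bank <- default_tube_bank(tube_spacing_mm, vein_offset_mm)
  if (!is.data.frame(tube_bank))   # e.g. column lists from a YAML config
    tube_bank <- as.data.frame(tube_bank, stringsAsFactors = FALSE)
  if (!is.data.frame(frame_schedule))
    frame_schedule <- as.data.frame(frame_schedule)
  need <- c("label", "diameter_mm", "x_mm", "y_mm", "role")
  if (!all(need %in% names(tube_bank)))
    stop("tube_bank needs columns ", paste(need, collapse = ", "))
  if (background_activity_kBq_cc < 0) stop("background activity must be >= 0")
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0")
  # non-overlap
  n <- nrow(tube_bank)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt((tube_bank$x_mm[i] - tube_bank$x_mm[j])^2 +
              (tube_bank$y_mm[i] - tube_bank$y_mm[j])^2)
    if (d < (tube_bank$diameter_mm[i] + tube_bank$diameter_mm[j]) / 2)
      stop(sprintf("tubes '%s' and '%s' overlap",
                   tube_bank$label[i], tube_bank$label[j]))
  }
  fs <- frame_schedule
  if (any(diff(fs$start_s) <= 0) ||
      any(fs$start_s[-1] < (fs$start_s + fs$duration_s)[-nrow(fs)] - 1e-9))
    stop("frame schedule must be increasing and non-overlapping")
  if (!is.null(fov_mm))  # YAML 1.1 reads a bare 'y' key as boolean TRUE
    names(fov_mm)[names(fov_mm) == "TRUE"] <- "y"
  margin <- 3 * psf_fwhm_mm
  if (is.null(fov_mm)) {
    rmax <- max(tube_bank$diameter_mm) / 2
    reach <- max(rmax + 25, 38)  # room for spill-out + background ring
    fov_mm <- list(
      x = c(min(tube_bank$x_mm) - reach - 8, max(tube_bank$x_mm) + reach + 8),
      y = c(-45, 45),
      z = c(-tube_length_mm / 2 - max(margin, 20),
            tube_length_mm / 2 + max(margin, 20)))
  }
  for (i in seq_len(n)) {
    r <- tube_bank$diameter_mm[i] / 2
    if (tube_bank$x_mm[i] - r - margin < fov_mm$x[1] ||
        tube_bank$x_mm[i] + r + margin > fov_mm$x[2] ||
        tube_bank$y_mm[i] - r - margin < fov_mm$y[1] ||
        tube_bank$y_mm[i] + r + margin > fov_mm$y[2])
      stop(sprintf("tube '%s' closer than 3 PSF FWHM to the field-of-view edge",
                   tube_bank$label[i]))
  }
  structure(list(tube_bank = tube_bank,
                 background_activity_kBq_cc = background_activity_kBq_cc,
                 psf_fwhm_mm = psf_fwhm_mm, voxel_size_mm = voxel_size_mm,
                 frame_schedule = fs, injection = injection,
                 flow_rate_mL_s = flow_rate_mL_s,
                 tube_length_mm = tube_length_mm, fov_mm = fov_mm,
                 noise = noise, seed = as.integer(seed),
                 tracer_half_life_min = tracer_half_life_min,
                 decay = decay),
            class = "phantom_spec")
}

#' Ground-truth arterial input function of the phantom
#'
#' Single well-mixed-chamber model: during the injection, tracer flows into
#' the mixing chamber at rate `A / T` while the chamber (volume `V`) is
#' flushed at the circuit flow `Q`; after the injection the chamber washes
#' out.  The concentration is the exact mono-exponential solution
#' `C(t) = A/(T Q) (1 - exp(-Q t / V))` for `t <= T`, then
#' `C(T) exp(-Q (t - T)/V)`, sampled at fine-bin midpoints.  Mass balance
#' holds by construction: `Q * integral(C) = A`.
#'
#' @param injection an [injection_model()].
#' @param flow_rate_mL_s circuit flow (mL/s).
#' @param t_end_s end of the sampled support (s); default 320.
#' @return a fine [tac()] in kBq/cc.
#' @export
generate_input_function <- function(injection, flow_rate_mL_s, t_end_s = 320) {
  stopifnot(inherits(injection, "injection_model"))
  if (!is.finite(flow_rate_mL_s) || flow_rate_mL_s <= 0)
    stop("non-physical flow rate")
  dt <- injection$sample_dt_s
  A <- injection$injected_activity_MBq * 1000  # kBq
  T_inj <- injection$injection_duration_s
  V <- injection$chamber_volume_mL
  Q <- flow_rate_mL_s
  starts <- seq(0, t_end_s - dt, by = dt)
  tm <- starts + dt / 2
  R <- A / T_inj  # kBq/s inflow during injection
  if (V <= dt / 100) {  # degenerate chamber: boxcar
    vals <- ifelse(tm < T_inj, R / Q, 0)
  } else {
    k <- Q / V
    c_end <- (R / Q) * (1 - exp(-k * T_inj))
    vals <- ifelse(tm < T_inj,
                   (R / Q) * (1 - exp(-k * tm)),
                   c_end * exp(-k * (tm - T_inj)))
  }
  tac(starts, dt, vals)
}

#' Venous curve from the arterial curve through the buffer compartment
#'
#' Convolves the arterial curve with the impulse response of a single
#' well-mixed buffer compartment, `(Q/V) exp(-Q t / V)`.  The kernel is
#' discretized with exact per-bin integrals and unit mass, so the AUC is
#' preserved while the peak is delayed and lowered.
#'
#' @param arterial fine arterial [tac()].
#' @param buffer_volume_mL buffer compartment volume (mL).
#' @param flow_rate_mL_s circuit flow (mL/s).
#' @return a fine [tac()] on the same grid.
#' @export
generate_vein_curve <- function(arterial, buffer_volume_mL, flow_rate_mL_s) {
  stopifnot_tac(arterial)
  dt <- fine_dt(arterial)
  if (buffer_volume_mL <= dt * flow_rate_mL_s / 100) return(arterial)
  k <- flow_rate_mL_s / buffer_volume_mL
  n <- nrow(arterial)
  nk <- min(n, ceiling(12 / (k * dt)))
  edges <- (0:nk) * dt
  h <- exp(-k * edges[-length(edges)]) - exp(-k * edges[-1])  # unit-mass bins
  v <- stats::convolve(arterial$value, rev(h), type = "open")[seq_len(n)]
  tac(arterial$frame_start_s, arterial$frame_duration_s, v,
      units = tac_units(arterial))
}

decay_factor <- function(t_s, half_life_min) 2^(-t_s / (half_life_min * 60))

#' Render the phantom as a dynamic PET image
#'
#' For each frame: the fine ground-truth curves are averaged over the frame
#' window; each tube cross-section is rasterized with fractional voxel
#' occupancy; the background compartment fills the rest of the volume; the
#' frame is convolved with the isotropic Gaussian PSF; and the configured
#' noise model is applied with the spec's seed.  Returns the image together
#' with the unblurred frame-averaged ground-truth TAC per tube.
#'
#' @param spec a [phantom_spec()].
#' @param arterial,venous fine ground-truth curves; defaults are generated
#'   from the spec's injection model.
#' @param subsamples in-plane sub-voxel sampling of the tube masks
#'   (default 7; rasterization error well below the PVE under study).
#' @return list with elements `image` (a [dynamic_image()]), `truth`
#'   (named list of ground-truth [tac()]s per tube, frame-averaged),
#'   `fine` (list with the fine `arterial` and `venous` curves) and `spec`.
#' @export
render_dynamic_image <- function(spec, arterial = NULL, venous = NULL,
                                 subsamples = 7L) {
  stopifnot(inherits(spec, "phantom_spec"))
  fs <- spec$frame_schedule
  t_end <- max(fs$start_s + fs$duration_s) + 20
  if (is.null(arterial))
    arterial <- generate_input_function(spec$injection, spec$flow_rate_mL_s,
                                        t_end_s = t_end)
  if (is.null(venous))
    venous <- generate_vein_curve(arterial, spec$injection$buffer_volume_mL,
                                  spec$flow_rate_mL_s)
  sched <- tac(fs$start_s, fs$duration_s, rep(0, nrow(fs)))
  art_f <- temporal_average(arterial, sched)
  ven_f <- temporal_average(venous, sched)

  h <- spec$voxel_size_mm
  dims <- c(ceiling(diff(spec$fov_mm$x) / h),
            ceiling(diff(spec$fov_mm$y) / h),
            ceiling(diff(spec$fov_mm$z) / h))
  grid <- image_grid(c(spec$fov_mm$x[1], spec$fov_mm$y[1], spec$fov_mm$z[1]),
                     h, dims)
  nt <- nrow(spec$tube_bank)
  occ <- vector("list", nt)
  for (i in seq_len(nt)) {
    tb <- spec$tube_bank[i, ]
    roi <- cylinder_roi(c(tb$x_mm, tb$y_mm, 0), tb$diameter_mm / 2,
                        spec$tube_length_mm, label = tb$label)
    occ[[i]] <- rasterize_roi(roi, grid, subsamples = subsamples)
  }
  occ_tot <- Reduce(`+`, occ)

  nf <- nrow(fs)
  t_mid <- fs$start_s + fs$duration_s / 2
  dec <- if (spec$decay == "physical")
    decay_factor(t_mid, spec$tracer_half_life_min) else rep(1, nf)

  sigma <- spec$psf_fwhm_mm / (2 * sqrt(2 * log(2)))
  Ks <- if (spec$psf_fwhm_mm > 0)
    lapply(1:3, function(ax) gaussian_band_matrix(dims[ax], sigma / h))
  arr <- array(0, c(dims, nf))
  bkg <- spec$background_activity_kBq_cc
  for (f in seq_len(nf)) {
    vol <- bkg * (1 - occ_tot)
    for (i in seq_len(nt)) {
      cf <- if (spec$tube_bank$role[i] == "vein") ven_f$value[f]
            else art_f$value[f]
      vol <- vol + cf * occ[[i]]
    }
    vol <- vol * dec[f]
    if (spec$psf_fwhm_mm > 0)
      for (ax in 1:3) vol <- blur_along_dim(vol, Ks[[ax]], ax)
    arr[, , , f] <- vol
  }
  img <- dynamic_image(arr, h, fs$start_s, fs$duration_s,
                       origin_mm = c(spec$fov_mm$x[1], spec$fov_mm$y[1],
                                     spec$fov_mm$z[1]))
  img <- add_noise(img, spec$noise, spec$seed)

  truth <- lapply(seq_len(nt), function(i) {
    v <- if (spec$tube_bank$role[i] == "vein") ven_f$value else art_f$value
    tac(fs$start_s, fs$duration_s, v * dec)
  })
  names(truth) <- spec$tube_bank$label
  list(image = img, truth = truth,
       fine = list(arterial = arterial, venous = venous), spec = spec)
}

#' Add frame-duration-dependent noise to a dynamic image
#'
#' The `"gaussian"` model adds zero-mean noise with standard deviation
#' `sigma = k * sqrt(max(value, floor) / frame_duration)`, emulating the
#' count-statistics trade-off between noise and temporal resolution: short
#' frames and hot voxels are noisier in absolute terms.  The model is a
#' pure function of `(image, model, seed)`; the caller's RNG state is left
#' untouched.
#'
#' @param image a [dynamic_image()].
#' @param model list with `model` (`"none"` or `"gaussian"`) and, for
#'   gaussian, `k` (kBq/cc per sqrt(kBq/cc/s); default 1.5) and `floor`
#'   (kBq/cc; default 0.1).
#' @param seed integer seed.
#' @return a [dynamic_image()] (bit-identical input for `model = "none"`).
#' @export
add_noise <- function(image, model = list(model = "gaussian"), seed = 1L) {
  stopifnot(inherits(image, "dynamic_image"))
  tag <- model$model
  if (is.null(tag)) stop("noise model needs a 'model' tag")
  if (tag == "none") return(image)
  if (tag != "gaussian") stop(sprintf("unknown noise model '%s'", tag))
  k <- if (is.null(model$k)) 1.5 else model$k
  floor_v <- if (is.null(model$floor)) 0.1 else model$floor
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  d <- dim(image$data)
  nvox <- prod(d[1:3])
  for (f in seq_len(d[4])) {
    vals <- image$data[, , , f]
    sigma <- k * sqrt(pmax(vals, floor_v) / image$frame_duration_s[f])
    image$data[, , , f] <- vals + stats::rnorm(nvox, sd = sigma)
  }
  image
}
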