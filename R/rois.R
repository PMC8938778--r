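#' Image sampling grid
#'
#' Regular voxel grid in image-space millimetre coordinates.  Voxel `i`
#' (1-based) along an axis has its centre at `origin + (i - 0.5) * spacing`,
#' i.e. `origin` is the low corner of the grid.
#'
#' @param origin_mm numeric length-3: low corner (mm).
#' @param spacing_mm numeric length-3 (or scalar): voxel spacing (mm).
#' @param dim integer length-3: voxel counts.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(origin_mm, spacing_mm, dim) {
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  stopifnot(length(origin_mm) == 3L, length(spacing_mm) == 3L,
            length(dim) == 3L, all(spacing_mm > 0), all(dim >= 1))
  structure(list(origin_mm = as.numeric(origin_mm),
                 spacing_mm = as.numeric(spacing_mm),
                 dim = as.integer(dim)),
            class = "image_grid")
}

grid_axis_centers <- function(grid, axis) {
  grid$origin_mm[axis] +
    (seq_len(grid$dim[axis]) - 0.5) * grid$spacing_mm[axis]
}

#' Cylindrical region of interest
#'
#' A z-axis-aligned (optionally annular) cylinder, matching the package's
#' coordinate convention that flow tubes run along z.  The true-size artery
#' region, the enlarged spill-out region and the background ring are all
#' instances of this type.
#'
#' @param center_mm numeric length-3 centre of the cylinder (mm).
#' @param radius_mm outer radius (mm).
#' @param length_mm axial length (mm).
#' @param inner_radius_mm inner radius (mm); `> 0` makes an annular
#'   cylinder (background ring).
#' @param label region label.
#' @return An object of class `cylinder_roi`.
#' @examples
#' a <- cylinder_roi(c(0, 0, 0), radius_mm = 4.75, length_mm = 20)
#' roi_volume_cc(a)   # pi * 4.75^2 * 20 / 1000
#' @export
cylinder_roi <- function(center_mm, radius_mm, length_mm,
                         inner_radius_mm = 0, label = "roi") {
  stopifnot(length(center_mm) == 3L)
  if (!is.finite(radius_mm) || radius_mm <= 0) stop("radius_mm must be positive")
  if (!is.finite(length_mm) || length_mm <= 0) stop("length_mm must be positive")
  if (inner_radius_mm < 0 || inner_radius_mm >= radius_mm)
    stop("inner_radius_mm must lie in [0, radius_mm)")
  structure(list(center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm, length_mm = length_mm,
                 inner_radius_mm = inner_radius_mm, label = label),
            class = "cylinder_roi")
}

#' @rdname cylinder_roi
#' @param roi a `cylinder_roi`.
#' @return `roi_volume_cc` returns the analytic volume in cc.
#' @export
roi_volume_cc <- function(roi) {
  stopifnot(inherits(roi, "cylinder_roi"))
  pi * (roi$radius_mm^2 - roi$inner_radius_mm^2) * roi$length_mm / 1000
}

#' Build the nested artery / spill-out / background-ring region scheme
#'
#' Given the true-size artery cylinder, constructs the enlarged spill-out
#' region (same centre and length, radius enlarged by `spill_margin_mm`)
#' and a background ring hugging it (inner radius equal to the spill-out
#' radius, outer radius `bkg_margin_mm` larger).  With a companion vein, a
#' single combined spill-out cylinder of radius `combined_radius_mm` is
#' centred midway between the two vessels and must contain both tubes; the
#' ring then surrounds the combined region.
#'
#' Volumes are analytic (the true geometry is assumed known, e.g. from CT).
#'
#' @param artery true-size artery [cylinder_roi()].
#' @param vein optional true-size vein [cylinder_roi()].
#' @param spill_margin_mm radial enlargement of the spill-out region (mm);
#'   default 15 (a radius 1.5 cm larger than the artery).
#' @param bkg_margin_mm radial width of the background ring (mm); default
#'   10.
#' @param combined_radius_mm radius of the combined artery+vein spill-out
#'   cylinder (mm); must contain both tubes.
#' @return An object of class `region_set` with elements `artery`,
#'   `spill_out`, `background_ring` and optionally `vein`.
#' @export
build_region_set <- function(artery, vein = NULL, spill_margin_mm = 15,
                             bkg_margin_mm = 10, combined_radius_mm = 25) {
  stopifnot(inherits(artery, "cylinder_roi"))
  if (is.null(vein)) {
    r_so <- artery$radius_mm + spill_margin_mm
    spill <- cylinder_roi(artery$center_mm, r_so, artery$length_mm,
                          label = "spill_out")
    ring <- cylinder_roi(artery$center_mm, r_so + bkg_margin_mm,
                         artery$length_mm, inner_radius_mm = r_so,
                         label = "background_ring")
    rs <- list(artery = artery, spill_out = spill, background_ring = ring,
               vein = NULL)
  } else {
    stopifnot(inherits(vein, "cylinder_roi"))
    if (abs(artery$length_mm - vein$length_mm) > 1e-9)
      stop("artery and vein regions must share the axial length")
    mid <- (artery$center_mm + vein$center_mm) / 2
    for (tube in list(artery, vein)) {
      d <- sqrt(sum((tube$center_mm[1:2] - mid[1:2])^2))
      if (d + tube$radius_mm > combined_radius_mm)
        stop("geometry error: combined spill-out cylinder does not contain ",
             tube$label)
    }
    spill <- cylinder_roi(c(mid[1:2], artery$center_mm[3]),
                          combined_radius_mm, artery$length_mm,
                          label = "spill_out")
    ring <- cylinder_roi(spill$center_mm, combined_radius_mm + bkg_margin_mm,
                         artery$length_mm, inner_radius_mm = combined_radius_mm,
                         label = "background_ring")
    rs <- list(artery = artery, spill_out = spill, background_ring = ring,
               vein = vein)
  }
  structure(rs, class = "region_set")
}

#' Rasterize a cylindrical ROI to a fractional occupancy map
#'
#' Computes, for every voxel, the fraction of its volume inside the
#' cylinder.  In-plane coverage is estimated by `subsamples x subsamples`
#' sub-voxel sampling of the (x, y) cross-section; axial coverage is the
#' exact 1-D overlap of each slice with the cylinder's z extent (exact for
#' the package's z-aligned cylinders), and the two factors multiply.
#'
#' @param roi a [cylinder_roi()].
#' @param grid an [image_grid()].
#' @param subsamples in-plane sub-voxel sampling factor per axis (default
#'   3, i.e. 3x3 points per voxel cross-section).
#' @return numeric array `dim(grid)` of occupancy fractions in `[0, 1]`.
#' @export
rasterize_roi <- function(roi, grid, subsamples = 3L) {
  stopifnot(inherits(roi, "cylinder_roi"), inherits(grid, "image_grid"))
  xs <- grid_axis_centers(grid, 1L)
  ys <- grid_axis_centers(grid, 2L)
  zs <- grid_axis_centers(grid, 3L)
  hx <- grid$spacing_mm[1]; hy <- grid$spacing_mm[2]; hz <- grid$spacing_mm[3]
  lo <- grid$origin_mm
  hi <- grid$origin_mm + grid$spacing_mm * grid$dim
  if (roi$center_mm[1] - roi$radius_mm < lo[1] - 1e-9 ||
      roi$center_mm[1] + roi$radius_mm > hi[1] + 1e-9 ||
      roi$center_mm[2] - roi$radius_mm < lo[2] - 1e-9 ||
      roi$center_mm[2] + roi$radius_mm > hi[2] + 1e-9 ||
      roi$center_mm[3] - roi$length_mm / 2 < lo[3] - 1e-9 ||
      roi$center_mm[3] + roi$length_mm / 2 > hi[3] + 1e-9)
    stop(sprintf("ROI '%s' extends outside the grid", roi$label))

  # in-plane fractional coverage by sub-voxel sampling
  off <- (seq_len(subsamples) - 0.5) / subsamples - 0.5
  occ_xy <- matrix(0, length(xs), length(ys))
  r2o <- roi$radius_mm^2
  r2i <- roi$inner_radius_mm^2
  for (dx in off * hx) {
    x2 <- (xs + dx - roi$center_mm[1])^2
    for (dy in off * hy) {
      y2 <- (ys + dy - roi$center_mm[2])^2
      d2 <- outer(x2, y2, `+`)
      occ_xy <- occ_xy + ((d2 <= r2o) & (d2 > r2i))
    }
  }
  occ_xy <- occ_xy / subsamples^2

  # exact axial overlap per slice
  z0 <- roi$center_mm[3] - roi$length_mm / 2
  z1 <- roi$center_mm[3] + roi$length_mm / 2
  zfrac <- pmax(0, pmin(zs + hz / 2, z1) - pmax(zs - hz / 2, z0)) / hz

  occ <- array(0, grid$dim)
  keep <- which(zfrac > 0)
  for (k in keep) occ[, , k] <- occ_xy * zfrac[k]
  occ
}

#' Extract a mean time-activity curve from a dynamic image
#'
#' Per frame, the occupancy-weighted mean of the voxel values inside the
#' ROI (fractional weighting by default; `"binary"` thresholds the
#' occupancy at 0.5 to mimic voxelized clinical contours).
#'
#' @param image a [dynamic_image()].
#' @param occupancy occupancy array from [rasterize_roi()] (or a logical /
#'   0-1 mask of the same spatial dimensions).
#' @param weighting `"fractional"` (default) or `"binary"`.
#' @return a [tac()] with the image's frame schedule.
#' @export
extract_tac <- function(image, occupancy, weighting = c("fractional", "binary")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(image, "dynamic_image"))
  d <- dim(image$data)
  if (!identical(dim(occupancy), d[1:3]))
    stop("occupancy map does not match the image's spatial dimensions")
  w <- if (weighting == "binary") as.numeric(occupancy >= 0.5)
       else as.numeric(occupancy)
  sw <- sum(w)
  if (sw == 0) stop("empty ROI: occupancy has no support",
                    if (weighting == "binary") " at binary threshold 0.5")
  nf <- d[4]
  mat <- matrix(image$data, nrow = prod(d[1:3]), ncol = nf)
  vals <- as.numeric(crossprod(mat, w)) / sw
  tac(image$frame_start_s, image$frame_duration_s, vals, units = image$units)
}

#' Split a cylinder ROI into axial replicate segments
#'
#' Mirrors the practice of contouring several consecutive axial segments
#' along a straight vessel and reporting a standard error over them.
#'
#' @param roi a [cylinder_roi()].
#' @param n number of equal-length segments.
#' @return list of `n` cylinder ROIs tiling the original length.
#' @export
split_roi_axially <- function(roi, n) {
  stopifnot(inherits(roi, "cylinder_roi"), n >= 1)
  seg <- roi$length_mm / n
  z0 <- roi$center_mm[3] - roi$length_mm / 2
  lapply(seq_len(n), function(i) {
    cylinder_roi(c(roi$center_mm[1:2], z0 + (i - 0.5) * seg),
                 roi$radius_mm, seg, roi$inner_radius_mm,
                 label = sprintf("%s_seg%d", roi$label, i))
  })
}
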