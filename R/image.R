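#' Dynamic (4-D) image container
#'
#' A 4-D voxel grid of activity concentrations (x, y, z, frame) with voxel
#' spacing, grid origin and the dynamic frame schedule.
#'
#' @param data 4-D numeric array (x, y, z, frame), kBq/cc.
#' @param spacing_mm voxel spacing, length 3 or scalar (mm).
#' @param frame_start_s,frame_duration_s frame schedule (seconds).
#' @param origin_mm low corner of the grid (mm); default `c(0, 0, 0)`.
#' @param units unit tag, default `"kBq/cc"`.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, spacing_mm, frame_start_s, frame_duration_s,
                          origin_mm = c(0, 0, 0), units = "kBq/cc") {
  if (length(dim(data)) != 4L) stop("data must be a 4-D array")
  nf <- dim(data)[4]
  if (length(frame_start_s) != nf || length(frame_duration_s) != nf)
    stop(sprintf("frame count mismatch: image has %d frames, schedule has %d",
                 nf, length(frame_start_s)))
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm),
                 frame_start_s = as.numeric(frame_start_s),
                 frame_duration_s = as.numeric(frame_duration_s),
                 units = units),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Dynamic image: %d x %d x %d voxels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %s mm, units %s\n",
              paste(format(x$spacing_mm, digits = 4), collapse = " x "),
              x$units))
  invisible(x)
}

#' @rdname image_grid
#' @param image a [dynamic_image()].
#' @return `image_grid_of` returns the [image_grid()] of a dynamic image.
#' @export
image_grid_of <- function(image) {
  stopifnot(inherits(image, "dynamic_image"))
  image_grid(image$origin_mm, image$spacing_mm, dim(image$data)[1:3])
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", "", path)

#' Read / write dynamic images as 4-D NIfTI plus JSON sidecar
#'
#' The canonical interchange format: one 4-D NIfTI file (4th dimension =
#' frames) and a JSON sidecar `<stem>.json` carrying the frame schedule,
#' units and grid origin.  Reading without the sidecar is an explicit
#' error; no frame schedule is ever silently assumed.
#'
#' @param image a [dynamic_image()].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `write_dynamic_image` returns `path` invisibly;
#'   `read_dynamic_image` returns a [dynamic_image()].
#' @export
write_dynamic_image <- function(image, path) {
  stopifnot(inherits(image, "dynamic_image"))
  nii <- RNifti::asNifti(image$data)
  RNifti::pixdim(nii) <- c(image$spacing_mm, 1)
  RNifti::writeNifti(nii, path)
  side <- list(frame_start_s = image$frame_start_s,
               frame_duration_s = image$frame_duration_s,
               units = image$units,
               origin_mm = image$origin_mm)
  jsonlite::write_json(side, paste0(sidecar_path(path), ".json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_dynamic_image
#' @export
read_dynamic_image <- function(path) {
  side_file <- paste0(sidecar_path(path), ".json")
  if (!file.exists(side_file))
    stop(sprintf("missing frame-schedule sidecar '%s'", side_file))
  side <- jsonlite::read_json(side_file, simplifyVector = TRUE)
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  spacing <- as.numeric(RNifti::pixdim(nii)[1:3])
  dynamic_image(arr, spacing,
                side$frame_start_s, side$frame_duration_s,
                origin_mm = if (!is.null(side$origin_mm)) side$origin_mm
                            else c(0, 0, 0),
                units = if (!is.null(side$units)) side$units else "kBq/cc")
}
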