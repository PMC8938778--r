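#' Time-activity curve
#'
#' A time-activity curve (TAC) is the framed concentration readout of a
#' dynamic PET acquisition: for each frame, a start time, a duration and a
#' mean concentration.  Frames are half-open intervals
#' `[start, start + duration)` in seconds; concentrations are in kBq/cc
#' unless another unit is tagged (reference DCE-CT curves carry HU).
#'
#' Finely sampled "reference" curves (e.g. the phantom ground truth) use the
#' same container with a short, uniform frame duration equal to the sampling
#' step, so that [auc()] and [temporal_average()] apply uniformly.
#'
#' @param frame_start_s numeric vector of frame start times (seconds),
#'   strictly increasing.
#' @param frame_duration_s numeric vector of frame durations (seconds),
#'   positive; frames must not overlap.
#' @param value numeric vector of mean concentrations per frame.
#' @param units unit tag recorded on the curve (default `"kBq/cc"`).
#' @return An object of class `tac`: a data frame with columns
#'   `frame_start_s`, `frame_duration_s`, `value` and a `units` attribute.
#' @examples
#' tac(seq(0, 280, by = 20), 20, rep(5, 15))
#' @export
tac <- function(frame_start_s, frame_duration_s, value, units = "kBq/cc") {
  n <- length(frame_start_s)
  if (n == 0L) stop("a time-activity curve needs at least one frame")
  if (length(frame_duration_s) == 1L) frame_duration_s <- rep(frame_duration_s, n)
  if (length(frame_duration_s) != n || length(value) != n)
    stop("frame_start_s, frame_duration_s and value must have equal length")
  if (any(!is.finite(frame_start_s)) || any(!is.finite(frame_duration_s)))
    stop("frame times must be finite")
  if (any(frame_duration_s <= 0)) stop("frame durations must be positive")
  if (n > 1L && any(diff(frame_start_s) <= 0))
    stop("frame starts must be strictly increasing")
  ends <- frame_start_s + frame_duration_s
  if (n > 1L) {
    bad <- which(frame_start_s[-1L] < ends[-n] - 1e-9)
    if (length(bad))
      stop(sprintf("overlapping frames at row %d", bad[1L] + 1L))
  }
  out <- data.frame(frame_start_s = as.numeric(frame_start_s),
                    frame_duration_s = as.numeric(frame_duration_s),
                    value = as.numeric(value))
  structure(out, class = c("tac", "data.frame"), units = units)
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("Time-activity curve: %d frames, %.4g-%.4g s, units %s\n",
              nrow(x), min(x$frame_start_s),
              max(x$frame_start_s + x$frame_duration_s),
              tac_units(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more frames\n", nrow(x) - 10L))
  invisible(x)
}

#' Frame midpoints of a TAC
#'
#' @param x a [tac()] object.
#' @return numeric vector of frame midpoint times in seconds.
#' @export
tac_midpoints <- function(x) x$frame_start_s + x$frame_duration_s / 2

#' @rdname tac
#' @param x a `tac` object.
#' @export
tac_units <- function(x) {
  u <- attr(x, "units")
  if (is.null(u)) "kBq/cc" else u
}

is_tac <- function(x) inherits(x, "tac")

stopifnot_tac <- function(x, arg = deparse(substitute(x))) {
  if (!is_tac(x)) stop(sprintf("'%s' must be a tac object", arg))
  invisible(x)
}

# uniform sampling step of a fine curve; errors if the grid is not uniform
fine_dt <- function(x, tol = 1e-6) {
  d <- x$frame_duration_s
  if (diff(range(d)) > tol * mean(d))
    stop("curve is not uniformly sampled")
  if (nrow(x) > 1L) {
    g <- diff(x$frame_start_s)
    if (max(abs(g - mean(d))) > tol * mean(d))
      stop("curve has gaps: frame starts do not tile the support")
  }
  mean(d)
}

#' Read / write TAC CSV files
#'
#' The on-disk format is a plain CSV with header columns `frame_start_s`,
#' `frame_duration_s` and `value` (the alias `value_kBq_per_cc` is accepted
#' and written).  Values round-trip losslessly to better than 1e-9 relative.
#'
#' @param path file path.
#' @return `read_tac_csv` returns a [tac()]; `write_tac_csv` returns `path`
#'   invisibly.
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df)[names(df) == "value_kBq_per_cc"] <- "value"
  need <- c("frame_start_s", "frame_duration_s", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("malformed TAC header in '%s': missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  tryCatch(tac(df$frame_start_s, df$frame_duration_s, df$value),
           error = function(e)
             stop(sprintf("invalid TAC in '%s': %s", path, conditionMessage(e))))
}

#' @rdname read_tac_csv
#' @param x a [tac()] object.
#' @export
write_tac_csv <- function(x, path) {
  stopifnot_tac(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("frame_start_s,frame_duration_s,value_kBq_per_cc", con)
  writeLines(sprintf("%.17g,%.17g,%.17g",
                     x$frame_start_s, x$frame_duration_s, x$value), con)
  invisible(path)
}
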