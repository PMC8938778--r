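# Independent oracles and shared fixtures for the test suite.
# Everything here deliberately avoids the package's own blur / rasterization
# code paths so that image-space conservation checks are genuinely
# independent.

# fractional in-plane disk mask on a square grid (10x10 sub-pixel sampling)
oracle_disk_mask <- function(xs, ys, cx, cy, r, r_inner = 0, sub = 10L) {
  off <- ((seq_len(sub) - 0.5) / sub - 0.5)
  m <- matrix(0, length(xs), length(ys))
  for (dx in off) for (dy in off) {
    d2 <- outer((xs + dx - cx)^2, (ys + dy - cy)^2, `+`)
    m <- m + ((d2 <= r^2) & (d2 > r_inner^2))
  }
  m / sub^2
}

# direct linear 2-D Gaussian convolution via zero-padded FFT
oracle_blur_2d <- function(field, fwhm, h = 1) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  rad <- ceiling(5 * sigma / h)
  k1 <- dnorm(seq(-rad, rad) * h, sd = sigma)
  k1 <- k1 / sum(k1)
  ker <- outer(k1, k1)
  n1 <- nrow(field) + 2 * rad
  n2 <- ncol(field) + 2 * rad
  pf <- matrix(0, n1, n2); pk <- matrix(0, n1, n2)
  pf[seq_len(nrow(field)), seq_len(ncol(field))] <- field
  pk[seq_len(2 * rad + 1), seq_len(2 * rad + 1)] <- ker
  conv <- Re(fft(fft(pf) * fft(pk), inverse = TRUE)) / (n1 * n2)
  conv[rad + seq_len(nrow(field)), rad + seq_len(ncol(field))]
}

# occupancy-weighted mean of a 2-D field
oracle_mask_mean <- function(field, mask) sum(field * mask) / sum(mask)

# shared phantom runs (expensive; built once per test session)
.phantom_cache <- new.env(parent = emptyenv())

phantom_run <- function(background = TRUE) {
  key <- if (background) "bg" else "nobg"
  if (is.null(.phantom_cache[[key]])) {
    cfg <- default_run_config()
    if (!background) cfg$phantom$background_activity_kBq_cc <- 0
    .phantom_cache[[key]] <- run_validation_experiment(cfg)
  }
  .phantom_cache[[key]]
}

# small single-tube phantom spec for fast rendering tests
small_phantom_spec <- function(...) {
  phantom_spec(
    tube_bank = data.frame(label = "tube", diameter_mm = 9.5,
                           x_mm = 0, y_mm = 0, role = "artery",
                           stringsAsFactors = FALSE),
    frame_schedule = data.frame(start_s = seq(0, 80, by = 20), duration_s = 20),
    fov_mm = list(x = c(-32, 32), y = c(-32, 32), z = c(-30, 30)),
    tube_length_mm = 30,
    ...)
}
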