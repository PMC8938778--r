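# Conservation-of-activity corrections: algebraic identities, image-space
# conservation oracles, and the recovery-coefficient comparator.

test_that("simple correction recovers total activity over the true volume", {
  # total activity A smeared over any enlarged region comes back as A/v_a
  A <- 37.5
  for (v_so in c(2, 5, 20)) {
    expect_equal(coa_correct_simple(A / v_so, v_so, v_a = 1.5), A / 1.5)
  }
  # no spill-out region at all: identity
  expect_equal(coa_correct_simple(c(1, 2, 3), 2, 2), c(1, 2, 3))
})

test_that("geometry preconditions are enforced", {
  expect_error(coa_correct_simple(1, 2, 0), "invalid geometry")
  expect_error(coa_correct_simple(1, 2, -1), "invalid geometry")
  expect_error(coa_correct_simple(1, 1, 2), "invalid geometry")
  expect_error(coa_correct_background(1, 2, 1, -0.5), "negative c_bkg")
  expect_silent(coa_correct_background(1, 2, 1, -0.5,
                                       allow_negative_background = TRUE))
  expect_error(rc_correct(1, 0), "invalid parameter")
  expect_error(rc_correct(1, 1.2), "invalid parameter")
})

test_that("background fixed point holds to machine precision", {
  set.seed(42)
  for (i in 1:25) {
    v_a <- runif(1, 0.1, 5)
    v_so <- v_a + runif(1, 0.1, 50)
    b <- runif(1, 0, 10)
    expect_equal(coa_correct_background(b, v_so, v_a, b), b, tolerance = 1e-14)
  }
})

test_that("reduction chain: Eq(2) -> Eq(1) and artery/vein -> Eq(2)", {
  set.seed(7)
  c_so <- runif(15, 0, 40); c_a <- runif(15, 0, 30)
  v_so <- 12; v_a <- 1.4
  expect_identical(coa_correct_background(c_so, v_so, v_a, 0),
                   coa_correct_simple(c_so, v_so, v_a))
  # vanishing vein signal with its volume excluded from the background term:
  # compare against Eq(2) computed over the remaining geometry
  v_v <- 1e-9
  m <- region_measurement(c_a, v_a, c_so, v_so, c_bkg = 1.4,
                          c_v = rep(0, 15), v_v = v_v)
  got <- coa_correct_artery_vein(m)
  want <- (c_so * v_so - 1.4 * (v_so - v_a - v_v)) / v_a
  expect_equal(got$c_a_corr, want, tolerance = 1e-12)
})

test_that("artery/vein symmetry splits the recovered activity equally", {
  c_a <- c(5, 10, 2); v <- 0.9
  m <- region_measurement(c_a, v, c_so = c(3, 6, 1.5), v_so = 10,
                          c_bkg = 0.5, c_v = c_a, v_v = v)
  got <- coa_correct_artery_vein(m)
  want <- (c(3, 6, 1.5) * 10 - 0.5 * (10 - 2 * v)) / (2 * v)
  expect_equal(got$c_a_corr, want)
  expect_equal(got$c_v_corr, want)
})

test_that("pre-arrival frames with zero signal product return zero", {
  m <- region_measurement(c_a = c(0, 4), v_a = 1, c_so = c(0.1, 3),
                          v_so = 8, c_bkg = 0, c_v = c(0, 2), v_v = 1)
  got <- coa_correct_artery_vein(m)
  expect_identical(got$c_a_corr[1], 0)
  expect_identical(got$c_v_corr[1], 0)
  expect_gt(got$c_a_corr[2], 0)
})

test_that("corrections are linear in the measured concentrations", {
  set.seed(11)
  c_so <- runif(10); c_a <- runif(10); c_v <- runif(10); b <- runif(10)
  k <- 3.7
  expect_equal(coa_correct_simple(k * c_so, 9, 2),
               k * coa_correct_simple(c_so, 9, 2))
  expect_equal(coa_correct_background(k * c_so, 9, 2, k * b),
               k * coa_correct_background(c_so, 9, 2, b))
  m1 <- region_measurement(c_a, 1, c_so, 9, b, c_v, 0.8)
  mk <- region_measurement(k * c_a, 1, k * c_so, 9, k * b, k * c_v, 0.8)
  expect_equal(coa_correct_artery_vein(mk)$c_a_corr,
               k * coa_correct_artery_vein(m1)$c_a_corr)
})

test_that("region_measurement validates vein configuration and geometry", {
  expect_error(region_measurement(1, 1, 1, 8, c_v = 1), "configuration error")
  expect_error(region_measurement(1, 1, 1, 1.5, c_v = 1, v_v = 1),
               "invalid geometry")
  expect_error(coa_correct_artery_vein(
    region_measurement(1, 1, 1, 8)), "configuration error")
})

test_that("blurred-cylinder conservation oracle: Eq(1) and Eq(2)", {
  # 9.5 mm cylinder at 10 kBq/cc on a 1 mm grid, 6 mm FWHM PSF, measured
  # over the +1.5 cm spill-out region -- built with an independent FFT
  # convolution, not the package renderer
  xs <- seq(-45, 45); ys <- xs
  r_a <- 4.75; r_so <- r_a + 15
  tube <- oracle_disk_mask(xs, ys, 0, 0, r_a)
  for (bkg in c(0, 1.4)) {
    field <- 10 * tube + bkg * (1 - tube)
    blurred <- oracle_blur_2d(field, fwhm = 6)
    m_so <- oracle_disk_mask(xs, ys, 0, 0, r_so)
    m_ring <- oracle_disk_mask(xs, ys, 0, 0, r_so + 10, r_inner = r_so)
    c_so <- oracle_mask_mean(blurred, m_so)
    v_a <- pi * r_a^2; v_so <- pi * r_so^2   # per unit length
    corr <- if (bkg == 0) coa_correct_simple(c_so, v_so, v_a)
            else coa_correct_background(c_so, v_so, v_a,
                                        oracle_mask_mean(blurred, m_ring))
    expect_lt(abs(corr - 10) / 10, 0.02)
    # uncorrected mean is substantially depressed toward background
    expect_lt(oracle_mask_mean(blurred, tube), 7)
  }
})

test_that("paired-tube oracle: Eq(6) recovers both curves at peak", {
  # two 6.35 mm tubes 2 cm apart carrying arterial (40) and lower venous
  # (25) peak values over a 1.4 kBq/cc background
  xs <- seq(-60, 60); ys <- seq(-50, 50)
  r <- 3.175; ca_true <- 40; cv_true <- 25; bkg <- 1.4
  art <- oracle_disk_mask(xs, ys, -10, 0, r)
  ven <- oracle_disk_mask(xs, ys, 10, 0, r)
  field <- ca_true * art + cv_true * ven + bkg * (1 - art - ven)
  blurred <- oracle_blur_2d(field, fwhm = 6)
  r_comb <- 25
  m_so <- oracle_disk_mask(xs, ys, 0, 0, r_comb)
  m_ring <- oracle_disk_mask(xs, ys, 0, 0, r_comb + 10, r_inner = r_comb)
  v_a <- pi * r^2; v_so <- pi * r_comb^2
  m <- region_measurement(
    c_a = oracle_mask_mean(blurred, art), v_a = v_a,
    c_so = oracle_mask_mean(blurred, m_so), v_so = v_so,
    c_bkg = oracle_mask_mean(blurred, m_ring),
    c_v = oracle_mask_mean(blurred, ven), v_v = v_a)
  got <- coa_correct_artery_vein(m)
  expect_lt(abs(got$c_a_corr - ca_true) / ca_true, 0.05)
  expect_lt(abs(got$c_v_corr - cv_true) / cv_true, 0.05)
})

test_that("cylinder recovery coefficient behaves as a recovery coefficient", {
  # limits
  expect_gt(recovery_coefficient_cylinder(600, 6), 0.99)
  expect_lt(recovery_coefficient_cylinder(0.05, 6), 0.01)
  # strictly increasing in diameter, decreasing in FWHM
  d <- c(2, 4, 6.35, 9.5, 12.7, 25.4)
  rc_d <- sapply(d, recovery_coefficient_cylinder, psf_fwhm_mm = 6)
  expect_true(all(diff(rc_d) > 0))
  f <- c(4, 5, 6, 7)
  rc_f <- sapply(f, function(x) recovery_coefficient_cylinder(9.5, x))
  expect_true(all(diff(rc_f) < 0))
  expect_true(all(rc_d > 0 & rc_d <= 1))
})

test_that("recovery coefficient matches refinement and Monte Carlo oracles", {
  rc <- recovery_coefficient_cylinder(9.5, 6)
  rc_fine <- recovery_coefficient_cylinder(9.5, 6, resolution_mm = 6 / 500)
  expect_lt(abs(rc - rc_fine), 1e-3)
  # rc = P(|U + Z| < r), U uniform on the disk, Z isotropic Gaussian
  set.seed(123)
  n <- 4e5
  r <- 9.5 / 2; sigma <- 6 / (2 * sqrt(2 * log(2)))
  u <- sqrt(runif(n)) * r; th <- runif(n, 0, 2 * pi)
  x <- u * cos(th) + rnorm(n, sd = sigma)
  y <- u * sin(th) + rnorm(n, sd = sigma)
  rc_mc <- mean(x^2 + y^2 < r^2)
  expect_lt(abs(rc - rc_mc), 4e-3)
})

test_that("rc correction is background-blind and inflates sub-background tails", {
  rc <- 0.5
  c_a <- c(40, 5, 1.2, 1.1)   # tail below a 1.4 background
  out <- rc_correct(c_a, rc)
  expect_equal(rc_correct(c_a, 1), c_a)
  expect_true(all(out > c_a))
  expect_true(all(out[3:4] > 1.4))
})
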