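test_that("rgb_to_luminance applies the luma weights on [0,1]", {
  px <- array(0L, dim = c(2, 2, 3))
  px[1, 1, ] <- c(255L, 255L, 255L)  # white
  px[1, 2, ] <- c(255L, 0L, 0L)      # pure red
  px[2, 1, ] <- c(0L, 255L, 0L)      # pure green
  px[2, 2, ] <- c(0L, 0L, 255L)      # pure blue
  L <- rgb_to_luminance(rgb_image(px))
  expect_equal(L$values[1, 1], 1.0)
  expect_equal(L$values[1, 2], 0.299)
  expect_equal(L$values[2, 1], 0.587)
  expect_equal(L$values[2, 2], 0.114)
  expect_equal(L$mean_luminance, mean(L$values), tolerance = 1e-12)
})

test_that("mean_center removes the mean to machine precision", {
  expect_equal(mean_center(luminance_field(matrix(0.7, 3, 5))),
               matrix(0, 3, 5))
  cb <- luminance_field(matrix(c(0, 1), 4, 4))
  expect_equal(sort(unique(as.vector(mean_center(cb)))), c(-0.5, 0.5))
  for (seed in 1:5) {
    expect_lt(abs(mean(mean_center(rand_field(7, 11, seed)))), 1e-12)
  }
})

test_that("autocorrelation_fft matches hand-summed values and Parseval", {
  # centered 2x2 checkerboard, circular: hand-summed over the 4 pixels
  x <- matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2)
  a <- autocorrelation_fft(x)
  expect_equal(acf_at(a, 0, 0), 0.25, tolerance = 1e-12)
  expect_equal(acf_at(a, 0, 1), -0.25, tolerance = 1e-12)
  expect_equal(acf_at(a, 1, 0), -0.25, tolerance = 1e-12)
  expect_equal(acf_at(a, 1, 1), 0.25, tolerance = 1e-12)

  # all-zero input -> all-zero field
  z <- autocorrelation_fft(matrix(0, 4, 4))
  expect_true(all(abs(z$values) < 1e-15))

  # lag (0,0) equals the mean of squares (Parseval), random 8x8
  for (seed in 1:10) {
    c8 <- rand_centered(8, 8, seed)
    expect_equal(acf_at(autocorrelation_fft(c8), 0, 0), mean(c8^2),
                 tolerance = 1e-12)
  }

  expect_error(autocorrelation_fft(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("circular ACF is symmetric under lag negation", {
  for (seed in 1:5) {
    a <- autocorrelation_fft(rand_centered(6, 9, seed))
    for (da in 0:5) for (db in 0:8) {
      expect_equal(acf_at(a, da, db), acf_at(a, -da, -db), tolerance = 1e-10)
    }
  }
})

test_that("direct summation agrees with the FFT route in both modes", {
  # hand case
  x <- matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2)
  d <- autocorrelation_direct(x, 1)
  f <- autocorrelation_fft(x)
  expect_equal(max_acf_diff(f, d, 1), 0, tolerance = 1e-12)

  # zeros everywhere
  dz <- autocorrelation_direct(matrix(0, 5, 5), 2)
  expect_true(all(abs(dz$values) < 1e-15, na.rm = TRUE))

  # 30 random 12x12 fields, both normalizations
  for (seed in 1:30) {
    z <- rand_centered(12, 12, seed)
    expect_lt(max_acf_diff(autocorrelation_fft(z),
                           autocorrelation_direct(z, 5), 5), 1e-10)
  }
  for (seed in 1:10) {
    z <- rand_centered(10, 12, seed + 100)
    expect_lt(max_acf_diff(autocorrelation_fft(z, "linear_unbiased"),
                           autocorrelation_direct(z, 4, "linear_unbiased"),
                           4), 1e-10)
  }

  expect_error(autocorrelation_direct(matrix(0, 4, 4), 4), "max_lag")
})

test_that("image_contrast reproduces analytic values", {
  # uniform -> 0
  for (lvl in c(0, 0.3, 1)) {
    r <- image_contrast(luminance_field(matrix(lvl, 8, 8)))
    expect_equal(r$variance_contrast, 0)
    expect_equal(r$rms_contrast, 0)
  }
  # balanced binary -> variance 0.25, rms 0.5
  cb <- luminance_field(matrix(c(0, 1), 16, 16))
  r <- image_contrast(cb)
  expect_equal(r$variance_contrast, 0.25, tolerance = 1e-12)
  expect_equal(r$rms_contrast, 0.5, tolerance = 1e-12)
  # sinusoidal grating -> A^2/2
  W <- 128
  for (A in c(0.1, 0.4)) {
    g <- luminance_field(matrix(0.5 + A * sin(2 * pi * 4 * (0:(W - 1)) / W),
                                16, W, byrow = TRUE))
    expect_equal(image_contrast(g)$variance_contrast, A^2 / 2,
                 tolerance = 1e-6)
  }
  # rms = sqrt(variance) always
  for (seed in 1:5) {
    r <- image_contrast(rand_field(9, 9, seed))
    expect_equal(r$rms_contrast, sqrt(r$variance_contrast), tolerance = 1e-12)
  }
  expect_error(image_contrast(luminance_field(matrix(0.5, 1, 1))),
               "single-pixel")
})

test_that("contrast is invariant to shifts, flips, rotation, and offset", {
  for (seed in 1:8) {
    f <- rand_field(15, 12, seed)
    v0 <- image_contrast(f)$variance_contrast
    m <- f$values
    variants <- list(
      m[c(6:15, 1:5), ],                      # circular row shift
      m[, c(8:12, 1:7)],                      # circular column shift
      m[nrow(m):1, ],                         # vertical flip
      m[, ncol(m):1],                         # horizontal flip
      t(m)[, nrow(m):1]                       # 90-degree rotation
    )
    for (v in variants) {
      expect_equal(image_contrast(luminance_field(v))$variance_contrast, v0,
                   tolerance = 1e-12)
    }
    # constant offset keeping values in [0,1]
    c_off <- (1 - max(m)) / 2
    expect_equal(image_contrast(luminance_field(m + c_off))$variance_contrast,
                 v0, tolerance = 1e-12)
  }
})

test_that("rms contrast is bounded by 0.5, attained only by balanced binary", {
  for (seed in 1:50) {
    expect_lte(image_contrast(rand_field(10, 10, seed))$rms_contrast, 0.5)
  }
  # unbalanced binary stays strictly below the bound
  ub <- matrix(0, 10, 10); ub[1:30] <- 1
  expect_lt(image_contrast(luminance_field(ub))$rms_contrast, 0.5)
})

test_that("radial profile: bin 0 is the variance contrast, decay over ell", {
  f <- generate_gaussian_field(96, 96, sigma = 0.1, ell = 8, seed = 5)
  cen <- mean_center(f)
  a <- autocorrelation_fft(cen)
  prof <- radial_acf_profile(a, n_bins = 24)
  expect_equal(prof$acov[prof$bin == 0], acf_at(a, 0, 0))
  expect_equal(prof$n_lags[prof$bin == 0], 1L)
  expect_equal(prof$acov[prof$bin == 0],
               image_contrast(f)$variance_contrast, tolerance = 1e-12)
  # monotone non-increasing over the first correlation length (radius ~ ell),
  # within sampling tolerance
  first <- prof$acov[prof$radius <= 8]
  expect_true(all(diff(first) <= 1e-4))
  # decayed well below the origin by a few correlation lengths
  expect_lt(prof$acov[which.min(abs(prof$radius - 24))],
            0.2 * prof$acov[1])

  # all-zero ACF -> all-zero profile
  z <- autocorrelation_fft(matrix(0, 8, 8))
  expect_true(all(abs(radial_acf_profile(z, 4)$acov) < 1e-15))
  expect_error(radial_acf_profile(a, 1), "n_bins")
})
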