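test_that("analytic kinds hit their known contrast", {
  # uniform
  u <- generate_image(synthetic_image_spec("uniform", 16, 16, level = 0.3))
  expect_equal(u$known_variance_contrast, 0)
  expect_equal(image_contrast(rgb_to_luminance(u$image))$variance_contrast,
               0, tolerance = 1e-10)

  # balanced checkerboard
  cb <- generate_image(synthetic_image_spec("checkerboard", 32, 32, tile = 8,
                                            levels = c(0, 1)))
  expect_equal(cb$known_variance_contrast, 0.25)
  rcb <- image_contrast(rgb_to_luminance(cb$image))
  expect_equal(rcb$variance_contrast, 0.25, tolerance = 1e-12)
  expect_equal(rcb$rms_contrast, 0.5, tolerance = 1e-12)

  # grating A = 0.4, k = 4: known A^2/2 = 0.08; measured within quantization
  g <- generate_image(synthetic_image_spec("grating", 256, 256,
                                           amplitude = 0.4, k = 4, seed = 7))
  expect_equal(g$known_variance_contrast, 0.08, tolerance = 1e-12)
  mg <- image_contrast(rgb_to_luminance(g$image))
  expect_lt(abs(mg$rms_contrast - sqrt(0.08)), 1e-3)

  # two-tone patches: p(1-p)(l2-l1)^2
  tt <- generate_image(synthetic_image_spec("two_tone_patches", 40, 40,
                                            levels = c(0.2, 0.8),
                                            fraction = 0.5, seed = 2))
  expect_equal(tt$known_variance_contrast, 0.25 * 0.6^2, tolerance = 1e-12)
  expect_lt(abs(image_contrast(rgb_to_luminance(tt$image))$rms_contrast -
                  sqrt(tt$known_variance_contrast)), 1e-3)
})

test_that("generation is deterministic per seed and validates parameters", {
  s <- synthetic_image_spec("gaussian_field", 32, 32, sigma = 0.1, ell = 3,
                            seed = 11)
  expect_identical(generate_image(s)$image$pixels,
                   generate_image(s)$image$pixels)
  s2 <- s; s2$seed <- 12L
  expect_false(identical(generate_image(s)$image$pixels,
                         generate_image(s2)$image$pixels))
  expect_error(synthetic_image_spec("grating", amplitude = 0.6), "amplitude")
  expect_error(synthetic_image_spec("uniform", level = 1.2), "level")
  expect_error(generate_gaussian_field(16, 16, sigma = 0.3), "clip")
})

test_that("gaussian field realizes its variance and correlation length", {
  # sigma = 0 -> uniform 0.5
  f0 <- generate_gaussian_field(8, 8, 0, 5, seed = 1)
  expect_equal(f0$values, matrix(0.5, 8, 8))

  # white field: plug-in variance is rescaled to sigma^2 exactly
  f <- generate_gaussian_field(64, 64, 0.1, 0, seed = 3)
  expect_equal(mean((f$values - mean(f$values))^2), 0.01, tolerance = 1e-10)

  # clipped fraction < 1e-3 in expectation at the sigma bound
  clip <- vapply(1:10, function(s) {
    mean(generate_gaussian_field(128, 128, 0.15, 0, s)$values %in% c(0, 1))
  }, numeric(1))
  expect_lt(mean(clip), 1e-3)

  # correlated field decays over ~ell (checked in test-contrast_core too)
  fc <- generate_gaussian_field(96, 96, 0.1, 6, seed = 5)
  a <- autocorrelation_fft(mean_center(fc))
  expect_gt(acf_at(a, 2, 0), 0.5 * acf_at(a, 0, 0))
  expect_lt(abs(acf_at(a, 20, 0)), 0.2 * acf_at(a, 0, 0))
})

test_that("generate_cohort writes a loadable, reproducible cohort", {
  td <- withr::local_tempdir()
  spec <- synthetic_cohort_spec(n_low = 4, n_high = 2, contrast_low = 0.1,
                                contrast_high = 0.25, within_sd = 0.02,
                                seed = 21)
  out <- generate_cohort(spec, file.path(td, "a"))
  expect_true(file.exists(out$catalog_path))
  expect_true(file.exists(out$truth_path))
  cat6 <- load_catalog(out$catalog_path)
  expect_equal(nrow(cat6), 6L)
  expect_equal(sum(cat6$condition == "high"), 2L)
  expect_true(all(file.exists(cat6$path)))

  # estimated contrast matches the truth targets within calibration tolerance
  truth <- read.csv(out$truth_path)
  for (i in seq_len(6)) {
    img <- load_image(cat6$path[i], source_id = cat6$image_id[i])
    est <- image_contrast(rgb_to_luminance(img))$rms_contrast
    expect_lt(abs(est - truth$target_rms_contrast[i]), 1e-3)
  }

  # bit-identical on regeneration
  out2 <- generate_cohort(spec, file.path(td, "b"))
  for (i in seq_len(6)) {
    expect_identical(load_image(load_catalog(out2$catalog_path)$path[i])$pixels,
                     load_image(cat6$path[i])$pixels)
  }
  expect_identical(out2$truth$target_rms_contrast,
                   out$truth$target_rms_contrast)
})

test_that("degenerate 1-vs-1 cohort always yields p = 1", {
  for (seed in 1:3) {
    spec <- synthetic_cohort_spec(n_low = 1, n_high = 1, seed = seed)
    res <- simulate_cohort_test(spec)
    expect_equal(res$p_pipeline, 1)
  }
})

test_that("cohort spec rejects targets beyond the image kind's range", {
  expect_error(synthetic_cohort_spec(contrast_high = 0.4), "cap")
  expect_error(synthetic_cohort_spec(kind = "gaussian_field",
                                     contrast_high = 0.2), "cap")
})
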