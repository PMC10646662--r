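# Synthetic paired-phantom generator

test_that("empty and degenerate phantom configurations behave analytically", {
  cfg0 <- phantom_config(n_lesions = 0, noise_sd_suv = 0, psf_fwhm_mm = 0,
                         grid_shape = c(16, 16, 12), seed = 3)
  s0 <- generate_subject(cfg0)
  expect_length(s0$masks, 0)
  expect_true(all(s0$image$values == cfg0$background_suv))
  expect_equal(nrow(s0$truth$lesions), 0)

  # fully degenerate generator: uniform lesion of SUV 8 on background 1
  cfg <- phantom_config(
    n_lesions = 1, background_suv = 1, lesion_mean_suv_range = c(8, 8),
    lesion_radius_range_mm = c(10, 10), texture_correlation_length_mm = 0,
    psf_fwhm_mm = 0, noise_sd_suv = 0, grid_shape = c(24, 24, 24),
    spacing_mm = c(2, 2, 2), seed = 5
  )
  s <- generate_subject(cfg)
  inside <- s$masks[[1]]$support
  expect_true(all(s$image$values[inside] == 8))
  expect_true(all(s$image$values[!inside] == 1))
})

test_that("spherical lesion ground-truth volume matches the voxelised mask", {
  cfg <- phantom_config(
    n_lesions = 1, lesion_radius_range_mm = c(10, 10),
    grid_shape = c(32, 32, 32), spacing_mm = c(2, 2, 2),
    psf_fwhm_mm = 0, noise_sd_suv = 0, seed = 11
  )
  s <- generate_subject(cfg)
  true_ml <- 4 / 3 * pi * 10^3 / 1000
  expect_equal(s$truth$lesions$volume_ml, true_ml, tolerance = 1e-12)
  mask_ml <- sum(s$masks[[1]]$support) * voxel_volume_ml(c(2, 2, 2))
  expect_lt(abs(mask_ml - true_ml), voxel_volume_ml(c(2, 2, 2)) * 20)
  # within one voxel-volume per surface shell is loose; enforce 3% here
  expect_lt(abs(mask_ml - true_ml) / true_ml, 0.03)
})

test_that("identical seeds give identical subjects and retests", {
  cfg <- phantom_config(seed = 21, grid_shape = c(32, 32, 24), n_lesions = 2)
  s1 <- generate_subject(cfg)
  s2 <- generate_subject(cfg)
  expect_identical(s1$image$values, s2$image$values)
  expect_identical(s1$truth$lesions, s2$truth$lesions)
  rc <- retest_config(wcv_true_pct = 12, seed = 9)
  r1 <- generate_retest(s1$image, s1$masks, s1$truth, rc)
  r2 <- generate_retest(s2$image, s2$masks, s2$truth, rc)
  expect_identical(r1$values, r2$values)
})

test_that("zero-variability retest reproduces the test image exactly", {
  cfg <- phantom_config(seed = 33, grid_shape = c(32, 32, 24), n_lesions = 2)
  s <- generate_subject(cfg)
  r <- generate_retest(s$image, s$masks, s$truth,
                       retest_config(wcv_true_pct = 0, bias_pct = 0,
                                     redraw_noise = FALSE, seed = 4))
  expect_identical(r$values, s$image$values)
})

test_that("pure bias scales lesion SUVmean exactly when background is zero", {
  cfg <- phantom_config(
    seed = 17, grid_shape = c(32, 32, 24), n_lesions = 2, background_suv = 0,
    noise_sd_suv = 0
  )
  s <- generate_subject(cfg)
  r <- generate_retest(s$image, s$masks, s$truth,
                       retest_config(wcv_true_pct = 0, bias_pct = 20,
                                     redraw_noise = FALSE, seed = 4))
  for (m in s$masks) {
    mt <- conventional_metrics(s$image, m)
    mr <- conventional_metrics(r, m)
    expect_equal(mr$suv_mean, 1.2 * mt$suv_mean, tolerance = 1e-12)
  }
})

test_that("injected within-subject CV is recovered from many simulated pairs", {
  # lesion-factor model only (no imaging): the empirical wCV of the paired
  # relative differences converges to the injected value
  cfg <- phantom_config(
    seed = 8, grid_shape = c(24, 24, 18), n_lesions = 1, psf_fwhm_mm = 0,
    noise_sd_suv = 0, texture_correlation_length_mm = 0,
    lesion_radius_range_mm = c(8, 10)
  )
  y_test <- numeric(0)
  y_retest <- numeric(0)
  for (i in 1:200) {
    cfg$seed <- 1000L + i
    s <- generate_subject(cfg)
    r <- generate_retest(s$image, s$masks, s$truth,
                         retest_config(wcv_true_pct = 10, bias_pct = 0,
                                       redraw_noise = FALSE, seed = 2000L + i))
    y_test <- c(y_test, conventional_metrics(s$image, s$masks[[1]])$suv_mean)
    y_retest <- c(y_retest, conventional_metrics(r, s$masks[[1]])$suv_mean)
  }
  w <- wcv(relative_differences(y_test, y_retest))
  expect_gt(w, 8)
  expect_lt(w, 12)
})

test_that("bias calibration follows the pair-mean closed form with noise off", {
  # with retest = (1 + b/100) * test, the pair-mean relative difference is
  # exactly B = 200 * beta / (2 + beta), beta = b / 100
  cfg <- phantom_config(seed = 71, grid_shape = c(24, 24, 18), n_lesions = 1,
                        background_suv = 0, noise_sd_suv = 0)
  s <- generate_subject(cfg)
  for (b in c(0, 10, 20)) {
    r <- generate_retest(s$image, s$masks, s$truth,
                         retest_config(wcv_true_pct = 0, bias_pct = b,
                                       redraw_noise = FALSE, seed = 1))
    yt <- conventional_metrics(s$image, s$masks[[1]])$suv_mean
    yr <- conventional_metrics(r, s$masks[[1]])$suv_mean
    beta <- b / 100
    expect_equal(relative_differences(yt, yr), 200 * beta / (2 + beta),
                 tolerance = 1e-10)
  }
})

test_that("cohort writer produces a consistent, deterministic dataset", {
  cfg <- phantom_config(seed = 42, grid_shape = c(24, 24, 18), n_lesions = 1)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  out1 <- generate_cohort(d1, n_subjects = 2, cfg = cfg, force = TRUE,
                          compress = FALSE)
  expect_error(generate_cohort(d1, n_subjects = 2, cfg = cfg), "exists")
  out2 <- generate_cohort(d2, n_subjects = 2, cfg = cfg, force = TRUE,
                          compress = FALSE)
  expect_identical(out1$pairing, out2$pairing)
  # byte-identical volumes for identical seeds
  f1 <- file.path(d1, "sub-01", "image_test.nii")
  f2 <- file.path(d2, "sub-01", "image_test.nii")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(nrow(out1$pairing), 2)

  # variable lesion counts: pairing rows equal total generated lesions
  d3 <- file.path(tempdir(), "cohort_c")
  on.exit(unlink(d3, recursive = TRUE), add = TRUE)
  out3 <- generate_cohort(d3, n_subjects = 5, cfg = cfg,
                          n_lesions_range = c(0, 3), force = TRUE,
                          compress = FALSE)
  n_lesions <- sum(vapply(out3$truth$subjects,
                          function(s) nrow(s$lesions), numeric(1)))
  expect_equal(nrow(out3$pairing), n_lesions)
})

test_that("impossible lesion packing is rejected", {
  cfg <- phantom_config(seed = 1, grid_shape = c(16, 16, 16),
                        spacing_mm = c(2, 2, 2), n_lesions = 10,
                        lesion_radius_range_mm = c(8, 8))
  expect_error(generate_subject(cfg), "overlap|without overlap")
})

test_that("configs that cannot yield includable lesions are rejected", {
  expect_error(
    phantom_config(lesion_radius_range_mm = c(2, 16)),
    "includability|1.50"
  )
  cfg <- phantom_config(lesion_radius_range_mm = c(2, 4), allow_small = TRUE,
                        grid_shape = c(24, 24, 18))
  expect_s3_class(cfg, "phantom_config")
})
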