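# Conventional metrics, discretisation, and the radiomics catalogue

test_that("conventional metrics follow their definitions", {
  # 10 voxels of 1 mL each, uniform SUV 2
  arr <- array(0, dim = c(12, 4, 4))
  arr[1:10, 2, 2] <- 2
  sup <- arr > 0
  img <- image_volume(arr, c(10, 10, 10))       # 1000 mm^3 = 1 mL voxels
  msk <- lesion_mask(sup, c(10, 10, 10))
  cm <- conventional_metrics(img, msk)
  expect_equal(cm$suv_max, 2)
  expect_equal(cm$suv_mean, 2)
  expect_equal(cm$volume_ml, 10)
  expect_equal(cm$suv_total, 20)

  # single voxel on the clinical grid
  arr2 <- array(0, dim = c(4, 4, 4))
  arr2[2, 2, 2] <- 7.3
  img2 <- image_volume(arr2, c(4.07, 4.07, 2))
  cm2 <- conventional_metrics(img2, lesion_mask(arr2 > 0, c(4.07, 4.07, 2)))
  expect_equal(cm2$volume_ml, 4.07 * 4.07 * 2 / 1000, tolerance = 1e-12)
  expect_equal(cm2$suv_total, 7.3 * 4.07 * 4.07 * 2 / 1000, tolerance = 1e-9)

  expect_error(
    conventional_metrics(img2, lesion_mask(array(FALSE, dim = c(4, 4, 4)),
                                           c(4.07, 4.07, 2))),
    "empty"
  )
})

test_that("conventional metrics equal a brute-force voxel loop", {
  les <- make_gradient_lesion(seed = 7)
  cm <- conventional_metrics(les$image, les$mask)
  vox <- which(les$mask$support)
  vals <- numeric(0)
  for (v in vox) vals <- c(vals, les$image$values[v])
  expect_equal(cm$suv_max, max(vals))
  expect_equal(cm$suv_mean, mean(vals))
  expect_equal(cm$volume_ml, length(vals) * prod(les$image$spacing_mm) / 1000)
  expect_equal(cm$suv_total, cm$suv_mean * cm$volume_ml, tolerance = 1e-15)
})

test_that("fixed-bin-width discretisation anchors edges at bin multiples", {
  arr <- array(0, dim = c(3, 1, 1) + c(0, 2, 2))
  arr[1:3, 2, 2] <- c(3.0, 3.19, 3.2)
  img <- image_volume(arr, c(1, 1, 1))
  msk <- lesion_mask(arr > 0, c(1, 1, 1))
  d <- discretise(img, msk, 0.2)
  expect_equal(d$levels[1:3, 2, 2], c(1L, 1L, 2L))
  expect_equal(d$n_levels, 2)

  # constant region
  arr[1:3, 2, 2] <- 4.4
  dc <- discretise(image_volume(arr, c(1, 1, 1)), msk, 0.2)
  expect_equal(unique(dc$levels[msk$support]), 1L)
  expect_equal(dc$n_levels, 1)

  # shifting by an exact multiple of the bin width preserves the level map
  les <- make_gradient_lesion(seed = 3)
  d1 <- discretise(les$image, les$mask, 0.25)
  img_shift <- image_volume(les$image$values + 4 * 0.25, c(1, 1, 1))
  d2 <- discretise(img_shift, les$mask, 0.25)
  expect_identical(d1$levels, d2$levels)
})

test_that("feature catalogue has the exact expected counts and names", {
  les <- make_gradient_lesion(seed = 5, side = 6)
  fv <- compute_features(les$image, les$mask)
  expect_length(fv, 107)
  fams <- table(vapply(strsplit(names(fv), "_"), `[`, character(1), 2))
  expect_equal(fams[["shape"]], 14)
  expect_equal(fams[["firstorder"]], 18)
  expect_equal(fams[["glcm"]], 24)
  expect_equal(fams[["gldm"]], 14)
  expect_equal(fams[["glrlm"]], 16)
  expect_equal(fams[["glszm"]], 16)
  expect_equal(fams[["ngtdm"]], 5)
  expect_false(any(duplicated(names(fv))))
  expect_true(all(is.finite(fv)))

  bank <- filter_bank()
  expect_length(bank, 16)
  expect_false(any(duplicated(vapply(bank, `[[`, character(1), "name"))))
  fv_all <- compute_features(les$image, les$mask, filters = bank)
  expect_length(fv_all, 107 + 1488)
  per_filter <- table(vapply(strsplit(names(fv_all), "_"), `[`, character(1), 1))
  expect_true(all(per_filter[setdiff(names(per_filter), "original")] == 93))
})

test_that("uniform regions return the documented degenerate feature values", {
  u <- uniform_lesion(value = 4, nvox_side = 3L)
  fv <- compute_features(u$image, u$mask)
  expect_equal(unname(fv["original_firstorder_Mean"]), 4)
  expect_equal(unname(fv["original_firstorder_Variance"]), 0)
  expect_equal(unname(fv["original_firstorder_Skewness"]), 0)
  expect_equal(unname(fv["original_firstorder_Kurtosis"]), 0)
  expect_equal(unname(fv["original_firstorder_Uniformity"]), 1)
  expect_equal(unname(fv["original_glcm_Correlation"]), 1)
  expect_equal(unname(fv["original_glcm_Imc1"]), 0)
  expect_equal(unname(fv["original_glcm_Imc2"]), 0)
  expect_equal(unname(fv["original_glcm_Contrast"]), 0)
  expect_equal(unname(fv["original_glcm_MCC"]), 1)
  expect_equal(unname(fv["original_ngtdm_Contrast"]), 0)
  expect_equal(unname(fv["original_ngtdm_Busyness"]), 0)
  expect_equal(unname(fv["original_ngtdm_Coarseness"]), 1e6)
  expect_equal(unname(fv["original_glszm_ZonePercentage"]), 1 / 27)
})

test_that("shape features are identical across filters and sane on a ball", {
  les <- make_gradient_lesion(seed = 9, side = 5)
  bank <- filter_bank()[c(1, 6, 12)]
  fv <- compute_features(les$image, les$mask, filters = bank)
  shp <- fv[grepl("^original_shape_", names(fv))]
  expect_length(shp, 14)
  # filtered outputs contain no shape entries at all
  expect_false(any(grepl("(exponential|log-sigma|wavelet).*_shape_", names(fv))))

  b <- ball_mask(10)
  sf <- shape_features(b)
  expect_gt(sf$Sphericity, 0.9)
  expect_lt(sf$Sphericity, 1)
  expect_equal(sf$MeshVolume, 4 / 3 * pi * 1000, tolerance = 0.05)
  expect_equal(sf$Maximum3DDiameter, 20, tolerance = 0.15)
  expect_equal(sf$Elongation, 1, tolerance = 0.05)
  expect_equal(sf$Flatness, 1, tolerance = 0.05)
})

test_that("first-order statistics match direct computation on random lesions", {
  les <- make_gradient_lesion(seed = 13, side = 5)
  fv <- compute_features(les$image, les$mask)
  vals <- les$image$values[les$mask$support]
  expect_equal(unname(fv["original_firstorder_Mean"]), mean(vals))
  expect_equal(unname(fv["original_firstorder_Median"]), median(vals))
  expect_equal(unname(fv["original_firstorder_Energy"]), sum(vals^2))
  expect_equal(unname(fv["original_firstorder_TotalEnergy"]),
               sum(vals^2) * prod(les$image$spacing_mm))
  expect_equal(unname(fv["original_firstorder_RootMeanSquared"]),
               sqrt(mean(vals^2)))
  expect_equal(unname(fv["original_firstorder_Variance"]),
               mean((vals - mean(vals))^2))
  expect_equal(unname(fv["original_firstorder_InterquartileRange"]),
               unname(quantile(vals, 0.75) - quantile(vals, 0.25)))
})

test_that("direction-merged texture features are invariant to 90-degree rotations", {
  set.seed(31)
  d <- c(7, 7, 7)
  lev <- array(NA_integer_, dim = d)
  core <- 2:6
  lev[core, core, core] <- sample.int(4, 125, replace = TRUE)
  ng <- 4L
  feats <- function(l) {
    nv <- sum(!is.na(l))
    c(unlist(glcm_features(glcm_matrix(l, ng))),
      unlist(glrlm_features(glrlm_matrix(l, ng), nv)),
      unlist(glszm_features(glszm_matrix(l, ng), nv)),
      unlist(gldm_features(gldm_matrix(l, ng))),
      unlist(ngtdm_features(ngtdm_matrix(l, ng))))
  }
  base <- feats(lev)
  rot_z <- aperm(lev, c(2, 1, 3))[d[2]:1, , , drop = FALSE]   # 90 deg about z
  rot_x <- aperm(lev, c(1, 3, 2))[, d[3]:1, , drop = FALSE]   # 90 deg about x
  expect_equal(feats(rot_z), base, tolerance = 1e-9)
  expect_equal(feats(rot_x), base, tolerance = 1e-9)
})
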