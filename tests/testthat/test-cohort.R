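# Cohort-level summaries, filter comparison, volume redundancy, pipeline

test_that("classification summaries count and percentage correctly", {
  rec <- function(cls, n) {
    data.frame(feature = sprintf("original_glcm_f%d", seq_len(n)),
               reliability_class = cls, stringsAsFactors = FALSE)
  }
  all_exc <- rec("excellent", 10)
  s <- classification_summary(all_exc, by_family = FALSE)
  expect_equal(s$counts$excellent, 10)
  expect_equal(s$good_or_excellent_pct, 100)

  mixed <- rbind(rec("excellent", 50), rec("good", 24), rec("moderate", 20),
                 rec("poor", 13))
  mixed$feature <- sprintf("original_glcm_f%d", seq_len(nrow(mixed)))
  sm <- classification_summary(mixed, by_family = FALSE)
  expect_equal(sm$n_features, 107)
  expect_equal(sm$good_or_excellent_pct, 100 * 74 / 107, tolerance = 1e-12)

  expect_error(classification_summary(mixed[0, ]), "no repeatability")
})

test_that("signed-rank test matches base R and handles zeros via Pratt", {
  set.seed(8)
  x <- rnorm(15)
  y <- x + rnorm(15, 0.3, 0.5)
  ours <- wilcoxon_signed_rank(x, y)
  base_p <- wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
  expect_equal(ours$p_value, base_p, tolerance = 1e-12)

  # all-zero differences: p = 1 with a tie flag
  z <- wilcoxon_signed_rank(1:10, 1:10)
  expect_equal(z$p_value, 1)
  expect_true(z$all_zero)

  # large-sample approximation stays close to base R when zeros are absent
  set.seed(9)
  x2 <- rnorm(60)
  y2 <- x2 + rnorm(60, 0.1, 0.4)
  ours2 <- wilcoxon_signed_rank(x2, y2)
  base2 <- wilcox.test(x2, y2, paired = TRUE, exact = FALSE,
                       correct = FALSE)$p.value
  expect_equal(ours2$p_value, base2, tolerance = 0.02)

  # uniformly shifted differences give the minimal-p extreme statistic
  shift <- wilcoxon_signed_rank(rep(1, 30) + 0.2, rep(1, 30))
  expect_equal(shift$statistic, sum(1:30))
})

test_that("filter comparison applies Bonferroni over the filter count", {
  set.seed(21)
  feats <- sprintf("glcm_f%02d", 1:93)
  orig <- data.frame(filter = "original", feature = feats,
                     icc = runif(93, 0.4, 0.95))
  tabs <- list(orig)
  for (f in sprintf("filter%02d", 1:16)) {
    icc <- orig$icc + rnorm(93, 0, 0.01)
    tabs[[length(tabs) + 1]] <- data.frame(filter = f, feature = feats,
                                           icc = icc)
  }
  res <- compare_filters(do.call(rbind, tabs))
  expect_equal(nrow(res), 16)
  expect_true(all(res$p_adj >= res$p_value))
  expect_true(all(res$p_adj <= 1))
  expect_equal(res$p_adj, pmin(1, 16 * res$p_value), tolerance = 1e-12)

  # identical ICCs: no significant filter, tie flag set
  same <- rbind(orig, transform(orig, filter = "flat"))
  res2 <- compare_filters(same)
  expect_false(any(res2$significant))
  expect_true(res2$tie_flag[res2$filter == "flat"])

  # a uniform +0.2 shift yields the one-sided extreme of the statistic
  up <- rbind(orig, transform(orig, filter = "up", icc = icc + 0.2))
  res3 <- compare_filters(up)
  row <- res3[res3$filter == "up", ]
  expect_equal(row$statistic, sum(1:93))
  expect_lt(row$p_value, 1e-10)
})

test_that("Bonferroni arithmetic example: p = 0.004 with m = 16", {
  expect_equal(min(1, 16 * 0.004), 0.064)
  expect_false(min(1, 16 * 0.004) < 0.05)
})

test_that("volume redundancy equals a rank-then-Pearson oracle", {
  set.seed(14)
  vols <- runif(20, 1.5, 40)
  tab <- data.frame(
    surrogate = vols * 2 + 1,
    decreasing = 100 - 3 * vols,
    noisy = rnorm(20),
    constant = rep(2, 20)
  )
  res <- volume_redundancy(tab, vols)
  expect_equal(res$abs_spearman[res$feature == "surrogate"], 1)
  expect_equal(res$abs_spearman[res$feature == "decreasing"], 1)
  expect_true(res$constant_flag[res$feature == "constant"])
  expect_true(is.na(res$abs_spearman[res$feature == "constant"]))
  expect_equal(res$abs_spearman[res$feature == "noisy"],
               abs(oracle_spearman(tab$noisy, vols)), tolerance = 1e-12)
  expect_error(volume_redundancy(tab[1:2, ], vols[1:2]), "at least 3")
})

test_that("the pipeline runs end to end, deterministically, with reports", {
  cfg <- phantom_config(seed = 55, grid_shape = c(40, 40, 28), n_lesions = 2,
                        lesion_radius_range_mm = c(9, 14))
  dd <- file.path(tempdir(), "pipe_ds")
  on.exit(unlink(dd, recursive = TRUE), add = TRUE)
  generate_cohort(dd, n_subjects = 3, cfg = cfg,
                  rcfg = retest_config(wcv_true_pct = 8, seed = 2),
                  force = TRUE)
  out1 <- file.path(tempdir(), "pipe_out1")
  out2 <- file.path(tempdir(), "pipe_out2")
  on.exit(unlink(c(out1, out2), recursive = TRUE), add = TRUE)
  res <- run_pipeline(dd, config = list(filters = "none"), out_dir = out1)
  expect_s3_class(res, "group_result")
  expect_equal(nrow(res$features), 2 * 6)   # 6 lesions, test + retest
  expect_true(all(c("conventional_SUVmean", "original_glcm_JointEntropy")
                  %in% names(res$features)))
  expect_equal(nrow(res$repeatability),
               ncol(res$features) - 3)
  # determinism of the full report
  run_pipeline(dd, config = list(filters = "none"), out_dir = out2)
  for (f in c("features.csv", "repeatability.csv", "classification.json")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  # report round-trip
  rt <- read_repeatability_report(out1)
  expect_equal(rt$feature, res$repeatability$feature)
  expect_equal(rt$wcv_pct, res$repeatability$wcv_pct, tolerance = 1e-8)
  # classification counts sum to the number of classified features
  cls <- res$classification
  expect_equal(sum(unlist(cls$counts)) + cls$n_unclassified, cls$n_features)
})

test_that("filtered pipeline produces the filter comparison table", {
  cfg <- phantom_config(seed = 77, grid_shape = c(32, 32, 24), n_lesions = 1,
                        lesion_radius_range_mm = c(8, 11))
  dd <- file.path(tempdir(), "pipe_ds_filt")
  on.exit(unlink(dd, recursive = TRUE), add = TRUE)
  generate_cohort(dd, n_subjects = 4, cfg = cfg,
                  rcfg = retest_config(wcv_true_pct = 10, seed = 3),
                  force = TRUE)
  res <- run_pipeline(dd, config = list(filters = c("square", "wavelet-LLL")))
  expect_equal(nrow(res$filter_comparison), 2)
  expect_setequal(res$filter_comparison$filter, c("square", "wavelet-LLL"))
  expect_true(all(res$filter_comparison$p_adj >=
                    res$filter_comparison$p_value - 1e-15))
  expect_false(is.null(res$volume_correlation))
  expect_true(all(res$volume_correlation$abs_spearman >= 0 |
                    res$volume_correlation$constant_flag, na.rm = TRUE))
})
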