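#' Paired relative differences (%)
#'
#' Relative difference per lesion between retest and test, with the pair
#' mean as denominator (Bland-Altman convention):
#' `d_i = 100 * (retest_i - test_i) / ((test_i + retest_i) / 2)`.
#' A `"test_value"` denominator (`100 * (retest - test) / test`) is
#' available for sensitivity analyses.
#'
#' @param y_test,y_retest numeric vectors of paired lesion-level values.
#' @param denominator `"pair_mean"` (default) or `"test_value"`.
#' @param ids optional lesion identifiers used in error messages.
#' @return Vector of relative differences in percent.
#' @export
relative_differences <- function(y_test, y_retest,
                                 denominator = c("pair_mean", "test_value"),
                                 ids = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(length(y_test) == length(y_retest))
  if (any(!is.finite(y_test)) || any(!is.finite(y_retest))) {
    stop("paired values must be finite", call. = FALSE)
  }
  ids <- ids %||% as.character(seq_along(y_test))
  den <- if (denominator == "pair_mean") (y_test + y_retest) / 2 else y_test
  bad <- den <= 0
  if (any(bad)) {
    stop(sprintf("non-positive denominator for lesion(s): %s",
                 paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  100 * (y_retest - y_test) / den
}

#' Within-subject coefficient of variation (%)
#'
#' Estimated from paired relative differences as
#' `wCV = sqrt(sum(d_i^2) / (2 n))`, the paired-replicate form of the
#' within-subject CV.
#'
#' @param d relative differences in percent (from [relative_differences()]).
#' @return wCV in percent.
#' @export
wcv <- function(d) {
  if (length(d) == 0L) stop("no paired differences supplied", call. = FALSE)
  sqrt(sum(d^2) / (2 * length(d)))
}

#' Repeatability coefficient (%)
#'
#' `RC = 1.96 * sqrt(2) * wCV`: the symmetric threshold within which 95% of
#' test-retest variability lies.
#'
#' @param wcv_pct within-subject CV in percent, >= 0.
#' @return RC in percent.
#' @export
repeatability_coefficient <- function(wcv_pct) {
  stopifnot(all(wcv_pct >= 0))
  1.96 * sqrt(2) * wcv_pct
}

#' 95% limits of agreement
#'
#' `[B - RC, B + RC]` around the mean relative difference B.
#'
#' @param b_pct mean relative difference in percent.
#' @param rc_pct repeatability coefficient in percent, >= 0.
#' @return Named vector `c(low, high)` in percent.
#' @export
limits_of_agreement <- function(b_pct, rc_pct) {
  stopifnot(rc_pct >= 0)
  c(low = b_pct - rc_pct, high = b_pct + rc_pct)
}

#' Intraclass correlation ICC(A,1) with 95% confidence interval
#'
#' Two-way mixed-effects model, absolute agreement, single rater/measurement,
#' computed from the two-way ANOVA mean squares of an n subjects x k
#' raters layout (here k = 2 scans):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`.
#' The confidence interval uses the F-distribution method of McGraw and
#' Wong with the Satterthwaite degrees of freedom for the denominator.
#' A consistency-type coefficient ICC(C,1) = `(MSR - MSE) / (MSR + MSE)`
#' (which ignores systematic offsets) is available via `type`.
#'
#' @param y_test,y_retest paired measurement vectors (n >= 3 recommended).
#' @param type `"agreement"` (default, ICC(A,1)) or `"consistency"`
#'   (ICC(C,1)).
#' @param conf_level confidence level (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, the mean squares, and a
#'   `degenerate` flag. Zero between-subject variance yields `NA` ICC with
#'   `degenerate = TRUE` (never silently 0); perfect agreement on
#'   non-constant data yields ICC 1 with a `[1, 1]` interval.
#' @export
icc_a1 <- function(y_test, y_retest, type = c("agreement", "consistency"),
                   conf_level = 0.95) {
  type <- match.arg(type)
  stopifnot(length(y_test) == length(y_retest))
  n <- length(y_test)
  if (n < 2L) stop("at least 2 paired observations required", call. = FALSE)
  k <- 2
  Y <- cbind(y_test, y_retest)
  grand <- mean(Y)
  row_m <- rowMeans(Y)
  col_m <- colMeans(Y)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((Y - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  out <- list(msr = msr, msc = msc, mse = mse, n = n, k = k,
              degenerate = FALSE)
  tol <- 1e-12 * max(1, abs(grand))^2
  if (msr <= tol && mse <= tol) {
    # no between-subject variance: reliability undefined
    out$icc <- NA_real_
    out$ci_low <- NA_real_
    out$ci_high <- NA_real_
    out$degenerate <- TRUE
    return(out)
  }
  if (mse <= tol && msc <= tol) {
    # perfect agreement on non-constant data
    out$icc <- 1
    out$ci_low <- 1
    out$ci_high <- 1
    return(out)
  }
  alpha <- 1 - conf_level
  if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    f1 <- stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f2 <- stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    out$icc <- icc
    out$ci_low <- (f_obs / f1 - 1) / (f_obs / f1 + k - 1)
    out$ci_high <- (f_obs * f2 - 1) / (f_obs * f2 + k - 1)
    return(out)
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v_num <- (a * msc + b * mse)^2
  v_den <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
  v <- v_num / v_den
  f_lower <- stats::qf(1 - alpha / 2, n - 1, v)
  f_upper <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_lower * mse) /
    (f_lower * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_upper * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_upper * msr)
  out$icc <- icc
  out$ci_low <- min(ci_low, icc)
  out$ci_high <- max(ci_high, icc)
  out
}

#' Reliability class from the ICC confidence-interval lower bound
#'
#' Koo-Li thresholds applied to the lower end of the 95% ICC confidence
#' interval: >= 0.9 excellent; [0.75, 0.9) good; [0.5, 0.75) moderate;
#' < 0.5 poor.
#'
#' @param ci_low ICC CI lower bound(s) in `[-1, 1]` (NA allowed).
#' @return Factor with levels excellent, good, moderate, poor.
#' @export
classify_icc <- function(ci_low) {
  cls <- ifelse(is.na(ci_low), NA_character_,
    ifelse(ci_low >= 0.9, "excellent",
      ifelse(ci_low >= 0.75, "good",
        ifelse(ci_low >= 0.5, "moderate", "poor"))))
  factor(cls, levels = c("excellent", "good", "moderate", "poor"))
}

#' Full repeatability record for one biomarker
#'
#' Combines the relative-difference statistics (B, wCV, RC, LOA) and the
#' ICC(A,1)-based reliability classification for one feature's paired
#' lesion-level measurements. Features whose pair means are not strictly
#' positive (possible for filtered radiomics features) get `NA`
#' relative-difference statistics with a flag; the ICC is still computed.
#'
#' @param y_test,y_retest paired measurement vectors.
#' @param feature_name name stored in the record.
#' @param denominator passed to [relative_differences()].
#' @return A one-row data frame (`repeatability_record`): feature, n,
#'   wcv_pct, rc_pct, b_pct, loa_low_pct, loa_high_pct, icc, icc_ci_low,
#'   icc_ci_high, reliability_class, icc_degenerate, relative_diff_defined.
#' @export
repeatability_record <- function(y_test, y_retest, feature_name = "feature",
                                 denominator = "pair_mean") {
  rel_ok <- TRUE
  d <- tryCatch(
    relative_differences(y_test, y_retest, denominator = denominator),
    error = function(e) {
      rel_ok <<- FALSE
      NULL
    }
  )
  if (rel_ok) {
    w <- wcv(d)
    rc <- repeatability_coefficient(w)
    b <- mean(d)
    loa <- limits_of_agreement(b, rc)
  } else {
    w <- rc <- b <- NA_real_
    loa <- c(low = NA_real_, high = NA_real_)
  }
  ic <- icc_a1(y_test, y_retest)
  data.frame(
    feature = feature_name, n = length(y_test), wcv_pct = w, rc_pct = rc,
    b_pct = b, loa_low_pct = unname(loa["low"]),
    loa_high_pct = unname(loa["high"]), icc = ic$icc,
    icc_ci_low = ic$ci_low, icc_ci_high = ic$ci_high,
    reliability_class = as.character(classify_icc(ic$ci_low)),
    icc_degenerate = ic$degenerate, relative_diff_defined = rel_ok,
    stringsAsFactors = FALSE
  )
}

#' Repeatability table for a feature table
#'
#' Applies [repeatability_record()] to every feature column of a paired
#' feature table (one test and one retest row per lesion).
#'
#' @param feature_table data frame from [extract_features()] (columns
#'   `subject_id`, `lesion_id`, `scan`, then features).
#' @param denominator passed to [relative_differences()].
#' @return Data frame with one repeatability record per feature.
#' @export
repeatability_table <- function(feature_table, denominator = "pair_mean") {
  stopifnot(all(c("subject_id", "lesion_id", "scan") %in% names(feature_table)))
  key <- interaction(feature_table$subject_id, feature_table$lesion_id,
                     drop = TRUE)
  test_rows <- feature_table$scan == "test"
  retest_rows <- feature_table$scan == "retest"
  ord_t <- order(key[test_rows])
  ord_r <- order(key[retest_rows])
  if (!identical(as.character(sort(key[test_rows])),
                 as.character(sort(key[retest_rows])))) {
    stop("feature table is not fully paired", call. = FALSE)
  }
  feats <- setdiff(names(feature_table), c("subject_id", "lesion_id", "scan"))
  recs <- lapply(feats, function(f) {
    yt <- feature_table[test_rows, f][ord_t]
    yr <- feature_table[retest_rows, f][ord_r]
    repeatability_record(yt, yr, feature_name = f,
                         denominator = denominator)
  })
  do.call(rbind, c(recs, list(make.row.names = FALSE)))
}
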