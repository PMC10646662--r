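#' Load a paired test-retest dataset directory
#'
#' Reads the `pairing.csv` table written by [generate_cohort()] (or prepared
#' by hand for user data: columns subject_id, lesion_id, test_path,
#' retest_path, mask_path, paths relative to the dataset directory) and
#' loads images and masks. The same delineation mask is applied to both
#' scans (registered grids); lesions whose mask is empty are excluded and
#' reported.
#'
#' @param dataset_dir dataset directory containing `pairing.csv`.
#' @return List with `pairs` (list of lesion-pair lists for
#'   [extract_features()]) and `excluded` (data frame).
#' @export
load_dataset <- function(dataset_dir) {
  pairing_path <- file.path(dataset_dir, "pairing.csv")
  if (!file.exists(pairing_path)) {
    stop(sprintf("no pairing.csv found in '%s'", dataset_dir), call. = FALSE)
  }
  tab <- utils::read.csv(pairing_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "lesion_id", "test_path", "retest_path", "mask_path")
  if (!all(need %in% names(tab))) {
    stop(sprintf("pairing.csv must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  pairs <- list()
  excluded <- data.frame(subject_id = character(0), lesion_id = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  img_cache <- new.env(parent = emptyenv())
  get_img <- function(rel) {
    if (!exists(rel, img_cache)) {
      p <- file.path(dataset_dir, rel)
      if (!file.exists(p)) stop(sprintf("missing image file '%s'", p), call. = FALSE)
      assign(rel, read_volume(p), img_cache)
    }
    get(rel, img_cache)
  }
  for (r in seq_len(nrow(tab))) {
    ti <- get_img(tab$test_path[r])
    ri <- get_img(tab$retest_path[r])
    mk <- read_mask(file.path(dataset_dir, tab$mask_path[r]),
                    lesion_id = tab$lesion_id[r])
    if (!identical(dim(ti$values), dim(ri$values)) ||
        !identical(dim(ti$values), dim(mk$support))) {
      stop(sprintf("grid mismatch for lesion '%s' of subject '%s'",
                   tab$lesion_id[r], tab$subject_id[r]), call. = FALSE)
    }
    if (!any(mk$support)) {
      excluded <- rbind(excluded, data.frame(
        subject_id = tab$subject_id[r], lesion_id = tab$lesion_id[r],
        reason = "empty mask", stringsAsFactors = FALSE
      ))
      next
    }
    pairs[[length(pairs) + 1]] <- list(
      subject_id = tab$subject_id[r], lesion_id = tab$lesion_id[r],
      test_image = ti, test_mask = mk, retest_image = ri, retest_mask = mk
    )
  }
  list(pairs = pairs, excluded = excluded)
}

#' Classification summary of repeatability records
#'
#' Counts and percentages of reliability classes, overall and per feature
#' family (the family is parsed from feature names of the form
#' `<filter>_<family>_<Name>`; other names are grouped as "other").
#'
#' @param records data frame from [repeatability_table()].
#' @param by_family also return per-family counts.
#' @return List with `counts`, `percentages`, `n_features`,
#'   `good_or_excellent_pct`, and (optionally) `by_family`.
#' @export
classification_summary <- function(records, by_family = TRUE) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no repeatability records supplied", call. = FALSE)
  }
  classes <- factor(records$reliability_class,
                    levels = c("excellent", "good", "moderate", "poor"))
  counts <- table(classes, useNA = "no")
  n <- nrow(records)
  out <- list(
    counts = as.list(counts),
    percentages = as.list(round(100 * as.numeric(counts) / n, 1)),
    n_features = n,
    n_unclassified = sum(is.na(classes)),
    good_or_excellent_pct = 100 * sum(counts[c("excellent", "good")]) / n
  )
  names(out$percentages) <- names(counts)
  if (by_family) {
    fam <- vapply(strsplit(records$feature, "_"), function(x) {
      if (length(x) >= 3L) x[2] else "other"
    }, character(1))
    out$by_family <- lapply(split(seq_len(n), fam), function(ix) {
      tb <- table(classes[ix], useNA = "no")
      as.list(tb)
    })
  }
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test. For n <= 25 non-zero differences (and no
#' ties) the exact null distribution is used; otherwise a normal
#' approximation with tie correction and Pratt handling of zero differences
#' (zeros are ranked, then their ranks discarded). All-zero differences
#' return p = 1 with a tie flag.
#'
#' @param x,y paired numeric vectors.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return List with `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_nonzero`, and `all_zero` flag.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  d <- x - y
  d <- d[is.finite(d)]
  nz <- d != 0
  if (!any(nz)) {
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L, all_zero = TRUE))
  }
  n_nz <- sum(nz)
  has_ties <- anyDuplicated(abs(d[nz])) > 0L
  if (n_nz <= exact_max && !has_ties) {
    r <- rank(abs(d[nz]))
    v <- sum(r[d[nz] > 0])
    p <- min(1, 2 * min(stats::psignrank(v, n_nz),
                        1 - stats::psignrank(v - 1, n_nz)))
    return(list(statistic = v, p_value = p, n_nonzero = n_nz,
                all_zero = FALSE))
  }
  # Pratt: rank all |d| including zeros, then drop zero ranks
  r_all <- rank(abs(d))
  r_nz <- r_all[nz]
  v <- sum(r_nz[d[nz] > 0])
  n <- length(d)
  ev <- sum(r_nz) / 2
  ties <- table(abs(d[nz]))
  n0 <- sum(!nz)
  var_v <- (n * (n + 1) * (2 * n + 1)) / 24 -
    n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (v - ev) / sqrt(var_v)
  list(statistic = v, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       n_nonzero = n_nz, all_zero = FALSE)
}

#' Compare filtered ICC distributions with the original image
#'
#' For each filter, a two-sided Wilcoxon signed-rank test compares the
#' paired per-feature ICC vector of that filter against the original-image
#' ICCs of the same (non-shape) features, with Bonferroni adjustment over
#' the number of filters: `p_adj = min(1, m * p)`.
#'
#' @param icc_table data frame with columns `filter`, `feature` (name
#'   without the filter prefix) and `icc`; must include filter "original".
#' @param alpha significance level applied after adjustment.
#' @return Data frame: filter, n_features, median_delta_icc, statistic,
#'   p_value, p_adj, significant, tie_flag.
#' @export
compare_filters <- function(icc_table, alpha = 0.05) {
  stopifnot(all(c("filter", "feature", "icc") %in% names(icc_table)))
  if (!"original" %in% icc_table$filter) {
    stop("icc_table must contain filter 'original'", call. = FALSE)
  }
  orig <- icc_table[icc_table$filter == "original", ]
  filters <- setdiff(unique(icc_table$filter), "original")
  m <- length(filters)
  rows <- lapply(filters, function(f) {
    cur <- icc_table[icc_table$filter == f, ]
    common <- intersect(cur$feature, orig$feature)
    xi <- cur$icc[match(common, cur$feature)]
    yi <- orig$icc[match(common, orig$feature)]
    ok <- is.finite(xi) & is.finite(yi)
    wt <- wilcoxon_signed_rank(xi[ok], yi[ok])
    p_adj <- min(1, m * wt$p_value)
    data.frame(
      filter = f, n_features = sum(ok),
      median_delta_icc = stats::median(xi[ok] - yi[ok]),
      statistic = wt$statistic, p_value = wt$p_value, p_adj = p_adj,
      significant = p_adj < alpha, tie_flag = wt$all_zero,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Volume redundancy of texture features
#'
#' Absolute Spearman rank correlation (tie-corrected ranks) of each feature
#' with conventional lesion volume. Constant features get `NA` with a flag.
#'
#' @param feature_values data frame or matrix of feature columns (one row
#'   per lesion).
#' @param volumes lesion volumes (mL), same length as rows.
#' @return Data frame: feature, abs_spearman, constant_flag.
#' @export
volume_redundancy <- function(feature_values, volumes) {
  feature_values <- as.data.frame(feature_values)
  stopifnot(nrow(feature_values) == length(volumes))
  if (nrow(feature_values) < 3L) {
    stop("at least 3 lesions are required", call. = FALSE)
  }
  rows <- lapply(names(feature_values), function(f) {
    v <- feature_values[[f]]
    if (stats::sd(v) == 0 || !all(is.finite(v))) {
      data.frame(feature = f, abs_spearman = NA_real_, constant_flag = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(
        feature = f,
        abs_spearman = abs(stats::cor(v, volumes, method = "spearman")),
        constant_flag = FALSE, stringsAsFactors = FALSE
      )
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' End-to-end repeatability pipeline for one dataset
#'
#' Loads a paired dataset, extracts conventional metrics and (optionally)
#' the radiomics catalogue under the requested filters, computes the
#' per-feature repeatability table, the classification summary, the
#' filter-effect comparison (when filters were used) and the
#' volume-redundancy screen, and (optionally) persists CSV/JSON reports.
#' Deterministic given the data and configuration.
#'
#' @param dataset_dir dataset directory (see [load_dataset()]).
#' @param config list of options: `bin_width` (0.2), `filters` ("none",
#'   "all", or a character vector of filter names), `radiomics` (TRUE),
#'   `target_mm` (2), `denominator` ("pair_mean"), `group_label`.
#' @param out_dir optional report directory (created if needed): writes
#'   `features.csv`, `repeatability.csv`, `classification.json`,
#'   `filter_comparison.csv`, `volume_correlation.csv`, `exclusions.csv`.
#' @return A `group_result` list: `group_label`, `features`,
#'   `repeatability`, `classification`, `filter_comparison`,
#'   `volume_correlation`, `excluded`.
#' @export
run_pipeline <- function(dataset_dir, config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(
    bin_width = 0.2, filters = "none", radiomics = TRUE, target_mm = 2.0,
    denominator = "pair_mean", group_label = NA_character_
  ), config)
  if (is.na(cfg$group_label)) {
    cfg_path <- file.path(dataset_dir, "config.yaml")
    if (file.exists(cfg_path)) {
      cfg$group_label <- yaml::read_yaml(cfg_path)$group_label %||% "unknown"
    } else {
      cfg$group_label <- "unknown"
    }
  }
  filt <- NULL
  if (identical(cfg$filters, "all")) {
    filt <- filter_bank()
  } else if (!identical(cfg$filters, "none") && length(cfg$filters)) {
    bank <- filter_bank()
    bank_names <- vapply(bank, `[[`, character(1), "name")
    missing <- setdiff(cfg$filters, bank_names)
    if (length(missing)) {
      stop(sprintf("unknown filter(s): %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    filt <- bank[bank_names %in% cfg$filters]
  }
  ds <- load_dataset(dataset_dir)
  if (length(ds$pairs) == 0L) stop("dataset contains no usable lesion pairs", call. = FALSE)
  features <- extract_features(ds$pairs, bin_width = cfg$bin_width,
                               filters = filt, radiomics = cfg$radiomics,
                               target_mm = cfg$target_mm)
  rep_tab <- repeatability_table(features, denominator = cfg$denominator)
  cls <- classification_summary(rep_tab)
  # filter comparison on radiomics ICCs
  fcomp <- NULL
  if (!is.null(filt)) {
    parsed <- parse_feature_names(rep_tab$feature)
    radio <- !is.na(parsed$filter) & parsed$family != "shape"
    icc_table <- data.frame(
      filter = parsed$filter[radio],
      feature = paste(parsed$family[radio], parsed$name[radio], sep = "_"),
      icc = rep_tab$icc[radio], stringsAsFactors = FALSE
    )
    fcomp <- compare_filters(icc_table)
  }
  # volume redundancy of original-image texture features
  vol_red <- NULL
  if (cfg$radiomics) {
    test_rows <- features$scan == "test"
    vols <- features$conventional_Volume[test_rows]
    parsed_cols <- parse_feature_names(names(features))
    tex <- which(!is.na(parsed_cols$filter) & parsed_cols$filter == "original" &
                   parsed_cols$family %in% c("glcm", "gldm", "glrlm", "glszm", "ngtdm"))
    if (length(tex) && sum(test_rows) >= 3L) {
      vol_red <- volume_redundancy(features[test_rows, tex, drop = FALSE], vols)
    }
  }
  result <- structure(
    list(group_label = cfg$group_label, config = cfg, features = features,
         repeatability = rep_tab, classification = cls,
         filter_comparison = fcomp, volume_correlation = vol_red,
         excluded = ds$excluded),
    class = "group_result"
  )
  if (!is.null(out_dir)) write_reports(result, out_dir)
  result
}

parse_feature_names <- function(x) {
  parts <- strsplit(x, "_")
  filter <- vapply(parts, function(p) if (length(p) >= 3L) p[1] else NA_character_,
                   character(1))
  family <- vapply(parts, function(p) if (length(p) >= 3L) p[2] else NA_character_,
                   character(1))
  name <- vapply(parts, function(p) {
    if (length(p) >= 3L) paste(p[-(1:2)], collapse = "_") else NA_character_
  }, character(1))
  known <- c("shape", "firstorder", "glcm", "gldm", "glrlm", "glszm", "ngtdm")
  bad <- !is.na(family) & !(family %in% known)
  filter[bad] <- NA_character_
  family[bad] <- NA_character_
  name[bad] <- NA_character_
  data.frame(filter = filter, family = family, name = name,
             stringsAsFactors = FALSE)
}

#' Persist pipeline reports
#'
#' @param result a `group_result` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_reports <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(result$repeatability,
                   file.path(out_dir, "repeatability.csv"), row.names = FALSE)
  jsonlite::write_json(result$classification,
                       file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$filter_comparison)) {
    utils::write.csv(result$filter_comparison,
                     file.path(out_dir, "filter_comparison.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$volume_correlation)) {
    utils::write.csv(result$volume_correlation,
                     file.path(out_dir, "volume_correlation.csv"),
                     row.names = FALSE)
  }
  if (nrow(result$excluded)) {
    utils::write.csv(result$excluded, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' Re-read a persisted repeatability report
#'
#' Round-trips the CSV written by [write_reports()] back into the in-memory
#' repeatability table.
#'
#' @param out_dir report directory.
#' @return Data frame with the repeatability records.
#' @export
read_repeatability_report <- function(out_dir) {
  utils::read.csv(file.path(out_dir, "repeatability.csv"),
                  stringsAsFactors = FALSE)
}
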