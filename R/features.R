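#' Radiomics feature extraction for one lesion
#'
#' Computes the 107-feature catalogue on the original image (14 shape, 18
#' first-order, 24 GLCM, 14 GLDM, 16 GLRLM, 16 GLSZM, 5 NGTDM) and, for each
#' requested filter, the 93 intensity-based features on the filtered image
#' (shape is computed once, on the unfiltered mask geometry). Inputs are
#' expected on the isotropic resampled grid. Texture features use a fixed
#' bin width discretisation and direction-merged matrices. Feature names are
#' namespaced as `<filter>_<family>_<Name>`, e.g.
#' `original_glcm_JointEntropy`, `wavelet-HLL_firstorder_Mean`.
#'
#' @param image an `image_volume`.
#' @param mask a non-empty `lesion_mask` on the same grid.
#' @param bin_width discretisation bin width (default SUV 0.2).
#' @param filters list of `filter_spec`s ([filter_bank()] for the full set),
#'   or `NULL` for the original image only.
#' @param crop_pad padding (voxels) kept around the lesion bounding box when
#'   cropping before filtering, so filter supports are not truncated.
#' @return Named numeric vector: 107 values without filters, plus 93 per
#'   filter (1595 for the full 16-filter bank).
#' @export
compute_features <- function(image, mask, bin_width = 0.2, filters = NULL,
                             crop_pad = 12L) {
  check_same_grid(image, mask)
  if (!any(mask$support)) stop("mask is empty", call. = FALSE)
  cr <- crop_to_mask(image, mask, pad = crop_pad)
  out <- c()
  sh <- shape_features(cr$mask)
  out <- c(out, stats::setNames(
    unlist(sh), paste0("original_shape_", names(sh))
  ))
  out <- c(out, intensity_features(cr$image, cr$mask, bin_width, "original"))
  for (spec in filters) {
    filt <- apply_filter(cr$image, spec)
    out <- c(out, intensity_features(filt, cr$mask, bin_width, spec$name))
  }
  out
}

# The 93 intensity-based features (first-order + five texture families) of
# one (possibly filtered) image.
intensity_features <- function(image, mask, bin_width, prefix) {
  vals <- image$values[mask$support]
  nvox <- length(vals)
  fo <- firstorder_features(vals, prod(image$spacing_mm), bin_width)
  disc <- discretise(image, mask, bin_width)
  lev <- disc$levels
  ng <- disc$n_levels
  feats <- c(
    stats::setNames(unlist(fo), paste0(prefix, "_firstorder_", names(fo))),
    named_family(glcm_features(glcm_matrix(lev, ng)), prefix, "glcm"),
    named_family(gldm_features(gldm_matrix(lev, ng)), prefix, "gldm"),
    named_family(glrlm_features(glrlm_matrix(lev, ng), nvox), prefix, "glrlm"),
    named_family(glszm_features(glszm_matrix(lev, ng), nvox), prefix, "glszm"),
    named_family(ngtdm_features(ngtdm_matrix(lev, ng)), prefix, "ngtdm")
  )
  feats
}

named_family <- function(lst, prefix, family) {
  stats::setNames(unlist(lst), paste0(prefix, "_", family, "_", names(lst)))
}

#' Expected feature counts of the catalogue
#'
#' @return Named integer vector of per-family counts plus the totals for the
#'   original image (107), per filter (93) and the full 16-filter bank
#'   (107 + 1488).
#' @export
feature_catalogue_counts <- function() {
  fam <- c(shape = 14L, firstorder = 18L, glcm = 24L, gldm = 14L,
           glrlm = 16L, glszm = 16L, ngtdm = 5L)
  c(fam,
    original_total = sum(fam),
    per_filter = sum(fam) - fam[["shape"]],
    filtered_total = 16L * (sum(fam) - fam[["shape"]]),
    full_total = sum(fam) + 16L * (sum(fam) - fam[["shape"]]))
}

#' Extract the feature table for a set of lesion pairs
#'
#' Runs conventional metrics (on the original grid) and the radiomics
#' catalogue (on the 2 mm isotropic resampled grid) for the test and retest
#' scan of every lesion pair, returning one row per (subject, lesion, scan).
#'
#' @param pairs list of lesion pairs; each element a list with `subject_id`,
#'   `lesion_id`, and `image_volume`/`lesion_mask` entries `test_image`,
#'   `test_mask`, `retest_image`, `retest_mask`.
#' @param bin_width discretisation bin width.
#' @param filters list of `filter_spec`s, or `NULL` for original only.
#' @param radiomics compute the radiomics catalogue (set `FALSE` for a
#'   conventional-metrics-only table).
#' @param target_mm isotropic resampling target (default 2 mm).
#' @return Data frame: `subject_id`, `lesion_id`, `scan` (test/retest),
#'   conventional metric columns (`conventional_SUVmax`, ...), then one
#'   column per radiomics feature.
#' @export
extract_features <- function(pairs, bin_width = 0.2, filters = NULL,
                             radiomics = TRUE, target_mm = 2.0) {
  rows <- list()
  for (p in pairs) {
    for (scan in c("test", "retest")) {
      img <- p[[paste0(scan, "_image")]]
      msk <- p[[paste0(scan, "_mask")]]
      cm <- conventional_metrics(img, msk)
      row <- c(
        conventional_SUVmax = cm$suv_max, conventional_SUVmean = cm$suv_mean,
        conventional_SUVtotal = cm$suv_total, conventional_Volume = cm$volume_ml
      )
      if (radiomics) {
        cr <- crop_to_mask(img, msk, pad = 14L)
        rimg <- resample_isotropic(cr$image, target_mm)
        rmsk <- resample_mask(cr$mask, target_mm)
        if (!any(rmsk$support)) {
          stop(sprintf("lesion '%s' is empty after resampling", msk$lesion_id),
               call. = FALSE)
        }
        row <- c(row, compute_features(rimg, rmsk, bin_width, filters))
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = p$subject_id, lesion_id = p$lesion_id, scan = scan,
        t(row), check.names = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
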