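#' Global SUV threshold segmentation
#'
#' Labels the connected components of the voxel set `{SUV >= threshold}`
#' (inclusive threshold; 26-connectivity by default). Each component is one
#' candidate lesion. An empty result is allowed.
#'
#' @param image an `image_volume` in SUV units.
#' @param suv_threshold global threshold (default SUV 3).
#' @param connectivity 26 (default) or 6.
#' @return A `segmentation`: list with `labels` (integer array, 0 =
#'   background), `n` components, and the grid geometry.
#' @export
threshold_segment <- function(image, suv_threshold = 3.0, connectivity = 26) {
  stopifnot(inherits(image, "image_volume"))
  fg <- image$values >= suv_threshold
  cc <- connected_components(fg, connectivity = connectivity)
  structure(
    list(labels = cc$labels, n = cc$n, spacing_mm = image$spacing_mm,
         origin_mm = image$origin_mm),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d component(s)\n", x$n))
  invisible(x)
}

#' Remove candidate lesions below a volume threshold
#'
#' Drops components whose volume (voxel count times voxel volume) is below
#' `min_volume_cm3`; the survivors are relabelled 1..k. Exclusions are
#' recorded in the `excluded` element.
#'
#' @param seg a `segmentation` from [threshold_segment()].
#' @param min_volume_cm3 minimum includable lesion volume (default 1.5 cm^3).
#' @return A `segmentation` with an `excluded` data frame
#'   (component, voxels, volume_cm3).
#' @export
filter_small_lesions <- function(seg, min_volume_cm3 = 1.5) {
  stopifnot(inherits(seg, "segmentation"))
  vox_ml <- voxel_volume_ml(seg$spacing_mm)   # 1 mL == 1 cm^3
  excluded <- data.frame(component = integer(0), voxels = integer(0),
                         volume_cm3 = numeric(0))
  if (seg$n == 0L) {
    seg$excluded <- excluded
    return(seg)
  }
  counts <- tabulate(seg$labels[seg$labels > 0L], nbins = seg$n)
  vols <- counts * vox_ml
  keep <- vols >= min_volume_cm3
  excluded <- data.frame(component = which(!keep), voxels = counts[!keep],
                         volume_cm3 = vols[!keep])
  relabel <- integer(seg$n)
  relabel[keep] <- seq_len(sum(keep))
  labels <- seg$labels
  pos <- labels > 0L
  labels[pos] <- relabel[labels[pos]]
  seg$labels <- labels
  seg$n <- sum(keep)
  seg$excluded <- excluded
  seg
}

#' Extract per-component masks from a segmentation
#'
#' @param seg a `segmentation`.
#' @param prefix lesion id prefix.
#' @return List of `lesion_mask` objects, one per component.
#' @export
segmentation_masks <- function(seg, prefix = "lesion") {
  lapply(seq_len(seg$n), function(i) {
    lesion_mask(seg$labels == i, seg$spacing_mm, seg$origin_mm,
                lesion_id = sprintf("%s_%02d", prefix, i))
  })
}

mask_centroid_mm <- function(mask) {
  idx <- arrayInd(which(mask$support), dim(mask$support))
  mask$origin_mm + (colMeans(idx) - 0.5) * mask$spacing_mm
}

#' Match test and retest lesions
#'
#' Pairs lesions across the two scans. Strategy `"by_id"` pairs masks whose
#' `lesion_id`s are equal (the pairing-table workflow, where a shared
#' delineation is applied to registered grids). Strategy `"centroid"` pairs
#' mutually nearest centroids within a distance cap. Unmatched lesions on
#' either scan are excluded and reported, mirroring lesions visible on one
#' scan only.
#'
#' @param test_masks,retest_masks lists of `lesion_mask`.
#' @param strategy `"by_id"` or `"centroid"`.
#' @param max_distance_mm centroid pairing cap (mm).
#' @return List with `pairs` (data frame: test_id, retest_id, distance_mm)
#'   and `excluded` (data frame: lesion_id, scan, reason).
#' @export
match_lesions <- function(test_masks, retest_masks,
                          strategy = c("by_id", "centroid"),
                          max_distance_mm = 20) {
  strategy <- match.arg(strategy)
  excl <- function(id, scan, reason) {
    data.frame(lesion_id = id, scan = scan, reason = reason,
               stringsAsFactors = FALSE)
  }
  excluded <- excl(character(0), character(0), character(0))
  if (strategy == "by_id") {
    tid <- vapply(test_masks, `[[`, character(1), "lesion_id")
    rid <- vapply(retest_masks, `[[`, character(1), "lesion_id")
    common <- intersect(tid, rid)
    pairs <- data.frame(test_id = common, retest_id = common,
                        distance_mm = 0, stringsAsFactors = FALSE)
    for (id in setdiff(tid, rid)) {
      excluded <- rbind(excluded, excl(id, "test", "absent on retest scan"))
    }
    for (id in setdiff(rid, tid)) {
      excluded <- rbind(excluded, excl(id, "retest", "absent on test scan"))
    }
    return(list(pairs = pairs, excluded = excluded))
  }
  tid <- vapply(test_masks, `[[`, character(1), "lesion_id")
  rid <- vapply(retest_masks, `[[`, character(1), "lesion_id")
  if (length(test_masks) == 0L || length(retest_masks) == 0L) {
    for (id in tid) excluded <- rbind(excluded, excl(id, "test", "absent on retest scan"))
    for (id in rid) excluded <- rbind(excluded, excl(id, "retest", "absent on test scan"))
    return(list(pairs = data.frame(test_id = character(0),
                                   retest_id = character(0),
                                   distance_mm = numeric(0)),
                excluded = excluded))
  }
  tc <- t(vapply(test_masks, mask_centroid_mm, numeric(3)))
  rc <- t(vapply(retest_masks, mask_centroid_mm, numeric(3)))
  dmat <- outer(seq_len(nrow(tc)), seq_len(nrow(rc)), Vectorize(function(i, j) {
    sqrt(sum((tc[i, ] - rc[j, ])^2))
  }))
  # ambiguity: a lesion with two equidistant nearest partners
  for (i in seq_len(nrow(dmat))) {
    mins <- which(abs(dmat[i, ] - min(dmat[i, ])) < 1e-9)
    if (length(mins) > 1L && min(dmat[i, ]) <= max_distance_mm) {
      stop(sprintf("ambiguous centroid match: test lesion '%s' is equidistant to retest lesions %s",
                   tid[i], paste(sQuote(rid[mins]), collapse = ", ")),
           call. = FALSE)
    }
  }
  nearest_r <- apply(dmat, 1, which.min)
  nearest_t <- apply(dmat, 2, which.min)
  pairs <- data.frame(test_id = character(0), retest_id = character(0),
                      distance_mm = numeric(0), stringsAsFactors = FALSE)
  matched_t <- logical(nrow(dmat))
  matched_r <- logical(ncol(dmat))
  for (i in seq_len(nrow(dmat))) {
    j <- nearest_r[i]
    if (nearest_t[j] == i && dmat[i, j] <= max_distance_mm) {
      pairs <- rbind(pairs, data.frame(
        test_id = tid[i], retest_id = rid[j], distance_mm = dmat[i, j],
        stringsAsFactors = FALSE
      ))
      matched_t[i] <- TRUE
      matched_r[j] <- TRUE
    }
  }
  for (i in which(!matched_t)) {
    excluded <- rbind(excluded, excl(tid[i], "test", "no mutual nearest partner within cap"))
  }
  for (j in which(!matched_r)) {
    excluded <- rbind(excluded, excl(rid[j], "retest", "no mutual nearest partner within cap"))
  }
  list(pairs = pairs, excluded = excluded)
}
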