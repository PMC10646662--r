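#' Conventional PET quantitative metrics for one lesion
#'
#' Computes the four conventional lesion-level metrics on the original
#' (non-resampled) grid: `suv_max`, `suv_mean`, `volume_ml` (voxel count
#' times voxel volume, in mL) and `suv_total`, defined as `suv_mean`
#' multiplied by the lesion volume (SUV * mL).
#'
#' @param image an `image_volume` in SUV units.
#' @param mask a non-empty `lesion_mask` on the same grid.
#' @return A `conventional_metrics` list with fields `suv_max`, `suv_mean`,
#'   `suv_total`, `volume_ml`.
#' @export
conventional_metrics <- function(image, mask) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "lesion_mask"))
  check_same_grid(image, mask)
  vals <- image$values[mask$support]
  if (length(vals) == 0L) {
    stop(sprintf("mask '%s' is empty", mask$lesion_id), call. = FALSE)
  }
  vol <- length(vals) * voxel_volume_ml(image$spacing_mm)
  m <- mean(vals)
  structure(
    list(suv_max = max(vals), suv_mean = m, suv_total = m * vol,
         volume_ml = vol),
    class = "conventional_metrics"
  )
}

#' @export
print.conventional_metrics <- function(x, ...) {
  cat(sprintf(
    "<conventional_metrics> SUVmax %.3g, SUVmean %.3g, SUVtotal %.3g SUV*mL, volume %.3g mL\n",
    x$suv_max, x$suv_mean, x$suv_total, x$volume_ml
  ))
  invisible(x)
}

#' Fixed-bin-width grey-level discretisation
#'
#' Maps masked intensities to integer grey levels using a constant bin width
#' with bin edges anchored at multiples of the bin width (absolute SUV bins,
#' not region-relative): `level(v) = floor(v / w) - floor(min / w) + 1`.
#' Levels are contiguous from 1; shifting all values by an exact multiple of
#' the bin width leaves the level map unchanged.
#'
#' @param image an `image_volume` (possibly filtered, values may be negative).
#' @param mask a non-empty `lesion_mask` on the same grid.
#' @param bin_width bin width in intensity units (default SUV 0.2).
#' @return List with `levels` (integer array, NA outside the mask),
#'   `n_levels` (number of occupied level slots, max level), and `bin_width`.
#' @export
discretise <- function(image, mask, bin_width = 0.2) {
  stopifnot(bin_width > 0)
  check_same_grid(image, mask)
  if (!any(mask$support)) stop("mask is empty", call. = FALSE)
  vals <- image$values
  base <- floor(min(vals[mask$support]) / bin_width)
  lev <- array(NA_integer_, dim = dim(vals))
  lev[mask$support] <- as.integer(floor(vals[mask$support] / bin_width) - base + 1)
  list(levels = lev, n_levels = max(lev, na.rm = TRUE), bin_width = bin_width)
}
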