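#' 3-D image volume in SUV units
#'
#' Light container for a 3-D scalar grid with physical voxel spacing and
#' origin, both in millimetres. Values are standardised uptake values
#' normalised to body weight (SUV_bw, dimensionless) unless stated otherwise.
#' Axis order is x, y, z throughout; voxel (i, j, k) has its centre at
#' `origin + (c(i, j, k) - 0.5) * spacing` (corner-anchored half-open voxel
#' convention).
#'
#' @param values numeric 3-D array.
#' @param spacing_mm numeric triple of strictly positive voxel sizes (mm).
#' @param origin_mm numeric triple, physical position of the volume corner (mm).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be three strictly positive numbers", call. = FALSE)
  }
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm))) {
    stop("`origin_mm` must be three finite numbers", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("image values must be finite", call. = FALSE)
  }
  structure(
    list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]
  ))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' Voxel volume in millilitres
#'
#' @param x an `image_volume` or a numeric spacing triple (mm).
#' @return Single voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(x) {
  sp <- if (inherits(x, "image_volume")) x$spacing_mm else as.numeric(x)
  prod(sp) / 1000
}

#' Binary lesion mask aligned to an image grid
#'
#' @param support logical or 0/1 3-D array on the same grid as its image.
#' @param spacing_mm voxel spacing (mm).
#' @param origin_mm grid origin (mm).
#' @param lesion_id identifier string.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(support, spacing_mm, origin_mm = c(0, 0, 0),
                        lesion_id = "lesion") {
  if (!is.array(support) || length(dim(support)) != 3L) {
    stop("`support` must be a 3-D array", call. = FALSE)
  }
  support <- array(as.logical(support), dim = dim(support))
  if (any(is.na(support))) stop("mask contains NA", call. = FALSE)
  structure(
    list(
      support = support, spacing_mm = as.numeric(spacing_mm),
      origin_mm = as.numeric(origin_mm), lesion_id = as.character(lesion_id)
    ),
    class = "lesion_mask"
  )
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf(
    "<lesion_mask> '%s': %d voxels (%.3g mL)\n", x$lesion_id,
    sum(x$support), sum(x$support) * voxel_volume_ml(x$spacing_mm)
  ))
  invisible(x)
}

check_same_grid <- function(image, mask) {
  if (!identical(dim(image$values), dim(mask$support))) {
    stop("image and mask are on different grids", call. = FALSE)
  }
  if (max(abs(image$spacing_mm - mask$spacing_mm)) > 1e-6) {
    stop("image and mask have different voxel spacing", call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert an activity-concentration volume to SUV (body weight)
#'
#' SUV_bw = tissue concentration (kBq/mL) divided by injected activity per
#' gram of body weight. With activity in MBq and weight in kg this is
#' `concentration * weight_kg * 1000 / (injected_MBq * 1000)`, i.e.
#' concentration times weight in grams over injected activity in kBq.
#'
#' @param activity_volume `image_volume` holding activity concentration in
#'   kBq/mL (decay correction assumed already applied).
#' @param injected_activity_mbq injected activity in MBq, > 0.
#' @param body_weight_kg patient body weight in kg, > 0.
#' @return `image_volume` in SUV_bw units.
#' @export
convert_to_suv <- function(activity_volume, injected_activity_mbq, body_weight_kg) {
  stopifnot(inherits(activity_volume, "image_volume"))
  if (!is.numeric(injected_activity_mbq) || length(injected_activity_mbq) != 1L ||
      !is.finite(injected_activity_mbq) || injected_activity_mbq <= 0) {
    stop("`injected_activity_mbq` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(body_weight_kg) || length(body_weight_kg) != 1L ||
      !is.finite(body_weight_kg) || body_weight_kg <= 0) {
    stop("`body_weight_kg` must be a single positive number", call. = FALSE)
  }
  weight_g <- body_weight_kg * 1000
  injected_kbq <- injected_activity_mbq * 1000
  image_volume(
    activity_volume$values * weight_g / injected_kbq,
    activity_volume$spacing_mm, activity_volume$origin_mm
  )
}

#' Read a NIfTI volume as an `image_volume`
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return `image_volume` with spacing taken from the NIfTI pixdim.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  image_volume(vals, spacing_mm = sp)
}

#' Write an `image_volume` to NIfTI
#'
#' @param x `image_volume` or `lesion_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "lesion_mask")) {
    vals <- array(as.integer(x$support), dim = dim(x$support))
  } else {
    vals <- x$values
  }
  attr(vals, "pixdim") <- x$spacing_mm
  img <- RNifti::asNifti(vals, datatype = if (is.integer(vals)) "uint8" else "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI mask as a `lesion_mask`
#'
#' @param path path to a binary NIfTI file.
#' @param lesion_id identifier to attach.
#' @return `lesion_mask`.
#' @export
read_mask <- function(path, lesion_id = basename(path)) {
  v <- read_volume(path)
  lesion_mask(v$values > 0.5, v$spacing_mm, v$origin_mm, lesion_id = lesion_id)
}
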