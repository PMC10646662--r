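# The 16-filter image bank: four monotone intensity transforms, Laplacian
# of Gaussian at sigma = 2, 3, 4, 5 mm (physical units), and the eight
# subbands of a one-level undecimated separable 3-D wavelet transform
# (Coiflet-1, replicate boundary). Intensity transforms are normalised so
# the output range matches the input maximum absolute value; the wavelet
# filters are scaled by 1/sqrt(2) per axis so the LLL subband preserves
# constants and detail subbands of a constant image are exactly zero.

.coif1_lo <- c(-0.01565572813546454, -0.0727326195128539, 0.38486484686420286,
               0.8525720202122554, 0.3378976624578092, -0.0727326195128539)
.coif1_hi <- rev(.coif1_lo) * c(1, -1, 1, -1, 1, -1)

#' Enumerate the 16-filter bank
#'
#' @return List of 16 `filter_spec` lists (`kind`, `name`, and for LoG the
#'   `sigma_mm`, for wavelets the `subband`), in a stable order: the four
#'   intensity transforms, LoG sigma 2..5 mm, wavelet LLL..HHH.
#' @export
filter_bank <- function() {
  specs <- list(
    list(kind = "exponential", name = "exponential"),
    list(kind = "logarithm", name = "logarithm"),
    list(kind = "square", name = "square"),
    list(kind = "square_root", name = "squareroot")
  )
  for (s in c(2, 3, 4, 5)) {
    specs[[length(specs) + 1]] <- list(kind = "log_sigma", sigma_mm = s,
                                       name = sprintf("log-sigma-%d-mm", s))
  }
  for (sub in apply(expand.grid(c("L", "H"), c("L", "H"), c("L", "H"))[, 3:1],
                    1, paste0, collapse = "")) {
    specs[[length(specs) + 1]] <- list(kind = "wavelet", subband = sub,
                                       name = paste0("wavelet-", sub))
  }
  lapply(specs, function(s) structure(s, class = "filter_spec"))
}

# FIR convolution along one axis with an arbitrary-length kernel; tap t
# reads source index i + t - offset, replicate boundary.
conv_axis_fir <- function(arr, k, axis, offset) {
  d <- dim(arr)
  n <- d[axis]
  out <- array(0, dim = d)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (t in seq_along(k)) {
    src <- pmin(pmax(seq_len(n) + t - offset, 1L), n)
    idx_t <- idx
    idx_t[[axis]] <- src
    out <- out + k[t] * do.call(`[`, c(list(arr), idx_t, list(drop = FALSE)))
  }
  out
}

wavelet_subband <- function(arr, subband) {
  lo <- .coif1_lo / sqrt(2)
  hi <- .coif1_hi / sqrt(2)
  letters3 <- strsplit(subband, "")[[1]]
  for (ax in 1:3) {
    k <- if (letters3[ax] == "L") lo else hi
    arr <- conv_axis_fir(arr, k, ax, offset = 4L)
  }
  arr
}

log_filter <- function(image, sigma_mm) {
  sp <- image$spacing_mm
  if (sigma_mm < max(sp)) {
    warning(sprintf(
      "LoG sigma (%.3g mm) is smaller than the voxel spacing (%.3g mm)",
      sigma_mm, max(sp)
    ), call. = FALSE)
  }
  sm <- gaussian_smooth(image$values, sigma_mm / sp)
  lap <- array(0, dim = dim(sm))
  for (ax in 1:3) {
    lap <- lap + conv_axis_fir(sm, c(1, -2, 1) / sp[ax]^2, ax, offset = 2L)
  }
  lap
}

#' Apply one image filter from the bank
#'
#' Intensity transforms (with `m = max(abs(values))`, or 1 when the image is
#' identically zero): square `(x / sqrt(m))^2`; square root
#' `sign(x) * sqrt(m * abs(x))`; logarithm `sign(x) * m * log(abs(x) + 1) /
#' log(m + 1)`; exponential `exp(x * log(m) / m)`. Laplacian of Gaussian:
#' Gaussian smoothing with sigma in mm followed by a finite-difference
#' Laplacian in physical units. Wavelet: one-level undecimated separable
#' Coiflet-1 transform; the subband letters select low/high pass along
#' x, y, z in that order.
#'
#' @param image an `image_volume` (isotropic grid recommended for LoG and
#'   wavelet filters).
#' @param spec a `filter_spec` from [filter_bank()].
#' @return Filtered `image_volume` (values may be negative).
#' @export
apply_filter <- function(image, spec) {
  stopifnot(inherits(image, "image_volume"), inherits(spec, "filter_spec"))
  x <- image$values
  m <- max(abs(x))
  if (m == 0) m <- 1
  out <- switch(spec$kind,
    exponential = exp(x * log(m) / m),
    logarithm = sign(x) * m * log(abs(x) + 1) / log(m + 1),
    square = (x / sqrt(m))^2,
    square_root = sign(x) * sqrt(m * abs(x)),
    log_sigma = log_filter(image, spec$sigma_mm),
    wavelet = wavelet_subband(x, spec$subband),
    stop(sprintf("unknown filter kind '%s'", spec$kind), call. = FALSE)
  )
  image_volume(out, image$spacing_mm, image$origin_mm)
}
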