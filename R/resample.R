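# Isotropic resampling: cubic B-spline interpolation for images (with the
# standard recursive prefilter so the spline interpolates the samples) and
# nearest-neighbour interpolation for binary masks. Output grids share the
# input origin; voxel centres sit at origin + (i - 0.5) * spacing.

# Cubic B-spline kernel.
bspline3 <- function(t) {
  a <- abs(t)
  out <- numeric(length(a))
  i1 <- a < 1
  out[i1] <- 2 / 3 - a[i1]^2 + a[i1]^3 / 2
  i2 <- a >= 1 & a < 2
  out[i2] <- (2 - a[i2])^3 / 6
  out
}

# Direct-to-coefficient prefilter (pole -2 + sqrt(3), gain 6), applied to
# every column of a matrix; mirror boundary handling.
bspline_prefilter_cols <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(m)
  z1 <- sqrt(3) - 2
  # exact whole-sample mirror initialisation of the causal recursion
  w <- numeric(n)
  w[1] <- 1
  w[n] <- z1^(n - 1)
  if (n > 2L) {
    k <- 1:(n - 2)
    w[k + 1] <- z1^k + z1^(2 * n - 2 - k)
  }
  w <- w / (1 - z1^(2 * n - 2))
  cp <- matrix(0, n, ncol(m))
  cp[1, ] <- crossprod(w, m)
  for (i in 2:n) cp[i, ] <- m[i, ] + z1 * cp[i - 1, ]
  cm <- matrix(0, n, ncol(m))
  cm[n, ] <- (z1 / (z1^2 - 1)) * (cp[n, ] + z1 * cp[n - 1, ])
  for (i in (n - 1):1) cm[i, ] <- z1 * (cm[i + 1, ] - cp[i, ])
  6 * cm
}

# Mirror an integer index into [1, n] (whole-sample symmetry about the ends).
mirror_index <- function(k, n) {
  if (n == 1L) return(rep(1L, length(k)))
  period <- 2L * (n - 1L)
  k <- (k - 1L) %% period
  k[k < 0] <- k[k < 0] + period
  k <- ifelse(k >= n, period - k, k)
  k + 1L
}

# Weight matrix mapping n_in samples (as B-spline coefficients) to values at
# continuous input indices `u` (1-based voxel index scale).
bspline_weight_matrix <- function(u, n_in) {
  W <- matrix(0, length(u), n_in)
  base <- floor(u)
  for (off in -1:2) {
    k <- base + off
    w <- bspline3(u - k)
    km <- mirror_index(as.integer(k), n_in)
    for (j in seq_along(u)) {
      W[j, km[j]] <- W[j, km[j]] + w[j]
    }
  }
  W
}

apply_axis_matrix <- function(arr, W, axis, prefilter = TRUE) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(arr, perm)
  m <- matrix(ap, nrow = d[axis])
  if (prefilter) m <- bspline_prefilter_cols(m)
  res <- W %*% m
  out_d <- c(nrow(W), d[setdiff(1:3, axis)])
  out <- array(res, dim = out_d)
  aperm(out, order(perm))
}

#' Resample an image volume to isotropic spacing with cubic B-splines
#'
#' Produces a grid with the requested isotropic spacing covering the input
#' physical extent (same origin; output voxel count is
#' `ceiling(n_in * spacing_in / target)` per axis). Image values are
#' interpolated with a cubic B-spline (including the interpolation
#' prefilter, so an aligned identity resample reproduces the input exactly
#' and linear ramps are preserved away from the borders).
#'
#' @param image an `image_volume`.
#' @param target_mm isotropic target spacing in mm (default 2).
#' @param interpolation `"bspline"` (default) or `"nearest"`.
#' @return Resampled `image_volume`.
#' @export
resample_isotropic <- function(image, target_mm = 2.0,
                               interpolation = c("bspline", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(image, "image_volume"), target_mm > 0)
  d <- dim(image$values)
  n_out <- pmax(1L, as.integer(ceiling(d * image$spacing_mm / target_mm)))
  arr <- image$values
  for (ax in 1:3) {
    x_out <- (seq_len(n_out[ax]) - 0.5) * target_mm
    u <- x_out / image$spacing_mm[ax] + 0.5
    if (interpolation == "bspline") {
      W <- bspline_weight_matrix(u, dim(arr)[ax])
      arr <- apply_axis_matrix(arr, W, ax, prefilter = TRUE)
    } else {
      k <- mirror_index(as.integer(round(u)), dim(arr)[ax])
      W <- matrix(0, n_out[ax], dim(arr)[ax])
      W[cbind(seq_along(k), k)] <- 1
      arr <- apply_axis_matrix(arr, W, ax, prefilter = FALSE)
    }
  }
  image_volume(arr, rep(target_mm, 3), image$origin_mm)
}

#' Resample a binary mask to isotropic spacing (nearest neighbour)
#'
#' Companion to [resample_isotropic()]: the mask is resampled to the same
#' grid with nearest-neighbour interpolation and stays strictly binary.
#'
#' @param mask a `lesion_mask`.
#' @param target_mm isotropic target spacing in mm.
#' @return Resampled `lesion_mask`.
#' @export
resample_mask <- function(mask, target_mm = 2.0) {
  stopifnot(inherits(mask, "lesion_mask"), target_mm > 0)
  d <- dim(mask$support)
  n_out <- pmax(1L, as.integer(ceiling(d * mask$spacing_mm / target_mm)))
  arr <- array(as.numeric(mask$support), dim = d)
  for (ax in 1:3) {
    x_out <- (seq_len(n_out[ax]) - 0.5) * target_mm
    u <- x_out / mask$spacing_mm[ax] + 0.5
    k <- mirror_index(as.integer(round(u)), dim(arr)[ax])
    W <- matrix(0, n_out[ax], dim(arr)[ax])
    W[cbind(seq_along(k), k)] <- 1
    arr <- apply_axis_matrix(arr, W, ax, prefilter = FALSE)
  }
  lesion_mask(arr > 0.5, rep(target_mm, 3), mask$origin_mm,
              lesion_id = mask$lesion_id)
}
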