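# Shared low-level helpers: separable convolution, connected components,
# neighbourhood offsets, bounding-box cropping.

# 13 unique 3-D direction offsets (half of the 26-neighbourhood).
unique_offsets_3d <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), , drop = FALSE]
  # keep one of each (+d, -d) pair: lexicographically positive
  keep <- off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
    (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0)
  off[keep, , drop = FALSE]
}

all_offsets_3d <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), , drop = FALSE]
}

# 1-D convolution of each line of `arr` along `axis` with kernel `k`
# (odd length), replicating edge values. Implemented by shifting whole
# arrays, so cost is length(k) passes over the volume.
convolve_axis <- function(arr, k, axis, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  d <- dim(arr)
  n <- d[axis]
  half <- (length(k) - 1L) / 2L
  out <- array(0, dim = d)
  idx_full <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (t in seq_along(k)) {
    shift <- t - 1L - half           # source index = target + shift
    src <- seq_len(n) + shift
    if (pad == "replicate") {
      src <- pmin(pmax(src, 1L), n)
      idx <- idx_full
      idx[[axis]] <- src
      out <- out + k[t] * do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    } else {
      ok <- src >= 1L & src <= n
      if (!any(ok)) next
      idx_src <- idx_full
      idx_src[[axis]] <- src[ok]
      idx_dst <- idx_full
      idx_dst[[axis]] <- which(ok)
      contrib <- array(0, dim = d)
      contrib <- do.call(`[<-`, c(
        list(contrib), idx_dst,
        list(do.call(`[`, c(list(arr), idx_src, list(drop = FALSE))))
      ))
      out <- out + k[t] * contrib
    }
  }
  out
}

gaussian_kernel_1d <- function(sigma_vox, truncate = 4) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(truncate * sigma_vox))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable Gaussian smoothing; sigma given per axis in voxels.
gaussian_smooth <- function(arr, sigma_vox, pad = "replicate") {
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) {
      arr <- convolve_axis(arr, gaussian_kernel_1d(sigma_vox[ax]), ax, pad = pad)
    }
  }
  arr
}

# Connected components of a logical 3-D array. connectivity 26 (default)
# or 6. Returns an integer label array (0 = background) and component count.
connected_components <- function(support, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  d <- dim(support)
  fg <- which(support)
  labels <- array(0L, dim = d)
  if (length(fg) == 0L) {
    return(list(labels = labels, n = 0L))
  }
  coord <- arrayInd(fg, d)
  pos <- array(0L, dim = d)
  pos[fg] <- seq_along(fg)          # voxel -> vertex id
  offsets <- if (connectivity == 26) {
    unique_offsets_3d()
  } else {
    matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3, byrow = TRUE)
  }
  edges_from <- integer(0)
  edges_to <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    nb <- coord
    nb[, 1] <- nb[, 1] + offsets[r, 1]
    nb[, 2] <- nb[, 2] + offsets[r, 2]
    nb[, 3] <- nb[, 3] + offsets[r, 3]
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    hit <- pos[lin] > 0L
    if (!any(hit)) next
    edges_from <- c(edges_from, which(ok)[hit])
    edges_to <- c(edges_to, pos[lin][hit])
  }
  g <- igraph::make_graph(edges = as.vector(rbind(edges_from, edges_to)),
                          n = length(fg), directed = FALSE)
  comp <- igraph::components(g)
  labels[fg] <- comp$membership
  list(labels = labels, n = comp$no)
}

# Bounding box of a logical array, optionally padded by `pad` voxels and
# clipped to the grid. Returns list of index ranges per axis.
bounding_box <- function(support, pad = 0L) {
  stopifnot(any(support))
  d <- dim(support)
  idx <- arrayInd(which(support), d)
  lapply(1:3, function(ax) {
    lo <- max(1L, min(idx[, ax]) - pad)
    hi <- min(d[ax], max(idx[, ax]) + pad)
    lo:hi
  })
}

crop_to_box <- function(arr, box) arr[box[[1]], box[[2]], box[[3]], drop = FALSE]

# Crop image + mask to the mask bounding box with padding (in voxels).
crop_to_mask <- function(image, mask, pad = 10L) {
  check_same_grid(image, mask)
  box <- bounding_box(mask$support, pad = pad)
  offs <- vapply(box, function(b) b[1] - 1L, integer(1))
  img <- image_volume(
    crop_to_box(image$values, box), image$spacing_mm,
    image$origin_mm + offs * image$spacing_mm
  )
  msk <- lesion_mask(
    crop_to_box(mask$support, box), mask$spacing_mm,
    img$origin_mm, lesion_id = mask$lesion_id
  )
  list(image = img, mask = msk)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
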