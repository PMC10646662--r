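# Grey-level texture matrices on a discretised lesion. All matrices use the
# 3-D 26-neighbourhood at Chebyshev distance 1 and are direction-merged:
# counts from all 13 unique directions are accumulated into a single matrix
# before any feature is computed. `levels` is an integer array with NA
# outside the lesion; levels run 1..n_levels.

shift_levels <- function(lev, off) {
  d <- dim(lev)
  out <- array(NA_integer_, dim = d)
  src <- lapply(1:3, function(ax) {
    s <- seq_len(d[ax]) + off[ax]
    s[s < 1 | s > d[ax]] <- NA
    s
  })
  ok <- lapply(src, function(s) which(!is.na(s)))
  if (any(vapply(ok, length, integer(1)) == 0L)) return(out)
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    lev[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

#' Grey-level co-occurrence matrix (merged, symmetric)
#'
#' Counts co-occurring level pairs over the 13 unique direction offsets of
#' the 26-neighbourhood at distance 1; each pair is counted in both orders,
#' so the matrix is symmetric.
#'
#' @param levels integer level array (NA outside the lesion).
#' @param n_levels number of grey levels.
#' @return `n_levels` x `n_levels` count matrix.
#' @export
glcm_matrix <- function(levels, n_levels) {
  P <- matrix(0, n_levels, n_levels)
  offs <- unique_offsets_3d()
  for (r in seq_len(nrow(offs))) {
    nb <- shift_levels(levels, offs[r, ])
    ok <- !is.na(levels) & !is.na(nb)
    if (!any(ok)) next
    a <- levels[ok]
    b <- nb[ok]
    cnt <- tabulate(a + (b - 1L) * n_levels, nbins = n_levels^2)
    M <- matrix(cnt, n_levels, n_levels)
    P <- P + M + t(M)
  }
  P
}

#' Grey-level run-length matrix (merged over 13 directions)
#'
#' A run is a maximal set of consecutive in-lesion voxels with the same
#' grey level along one of the 13 unique directions; runs from all
#' directions are accumulated into one matrix.
#'
#' @inheritParams glcm_matrix
#' @return `n_levels` x `max_run_length` count matrix.
#' @export
glrlm_matrix <- function(levels, n_levels) {
  d <- dim(levels)
  idx <- which(!is.na(levels))
  coord <- arrayInd(idx, d)
  lv <- levels[idx]
  offs <- unique_offsets_3d()
  n_vox <- length(idx)
  max_len <- max(d)
  P <- matrix(0, n_levels, max_len)
  big <- max(d) + 2L
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    ax <- which(off != 0)[1]
    t_par <- coord[, ax] * off[ax]
    base <- coord - outer(t_par, off)      # constant along each line
    key <- (base[, 1] + big) + (2L * big) * (base[, 2] + big) +
      (2L * big)^2 * (base[, 3] + big)
    ord <- order(key, t_par)
    k <- key[ord]
    t_o <- t_par[ord]
    l_o <- lv[ord]
    brk <- c(TRUE, k[-1] != k[-n_vox] | t_o[-1] != t_o[-n_vox] + 1L |
               l_o[-1] != l_o[-n_vox])
    starts <- which(brk)
    lens <- diff(c(starts, n_vox + 1L))
    gl <- l_o[starts]
    cnt <- tabulate(gl + (lens - 1L) * n_levels, nbins = n_levels * max_len)
    P <- P + matrix(cnt, n_levels, max_len)
  }
  last <- max(which(colSums(P) > 0))
  P[, seq_len(last), drop = FALSE]
}

#' Grey-level size-zone matrix
#'
#' Zones are 26-connected components of voxels sharing one grey level;
#' the matrix counts zones by (level, zone size). Direction-independent.
#'
#' @inheritParams glcm_matrix
#' @return `n_levels` x `max_zone_size` count matrix.
#' @export
glszm_matrix <- function(levels, n_levels) {
  sizes <- list()
  for (g in seq_len(n_levels)) {
    sup <- !is.na(levels) & levels == g
    if (!any(sup)) {
      sizes[[g]] <- integer(0)
      next
    }
    cc <- connected_components(sup, connectivity = 26)
    sizes[[g]] <- tabulate(cc$labels[cc$labels > 0L], nbins = cc$n)
  }
  max_size <- max(1L, max(unlist(sizes), 0L))
  P <- matrix(0, n_levels, max_size)
  for (g in seq_len(n_levels)) {
    if (length(sizes[[g]])) {
      cnt <- tabulate(sizes[[g]], nbins = max_size)
      P[g, ] <- P[g, ] + cnt
    }
  }
  P
}

#' Grey-level dependence matrix
#'
#' For each in-lesion voxel, the dependence is one plus the number of
#' 26-neighbours (within the lesion) whose level differs by at most `alpha`
#' from the centre level; the matrix counts voxels by (level, dependence).
#'
#' @inheritParams glcm_matrix
#' @param alpha level-difference tolerance (default 0).
#' @return `n_levels` x `max_dependence` count matrix.
#' @export
gldm_matrix <- function(levels, n_levels, alpha = 0) {
  d <- dim(levels)
  dep <- array(0L, dim = d)
  offs <- all_offsets_3d()
  for (r in seq_len(nrow(offs))) {
    nb <- shift_levels(levels, offs[r, ])
    hit <- !is.na(levels) & !is.na(nb) & abs(levels - nb) <= alpha
    dep <- dep + hit
  }
  ok <- !is.na(levels)
  j <- dep[ok] + 1L
  g <- levels[ok]
  max_dep <- max(j)
  cnt <- tabulate(g + (j - 1L) * n_levels, nbins = n_levels * max_dep)
  matrix(cnt, n_levels, max_dep)
}

#' Neighbourhood grey-tone difference matrix
#'
#' For each grey level i: `n_i` is the number of in-lesion voxels with that
#' level that have at least one in-lesion 26-neighbour, and `s_i` is the sum
#' of absolute differences between the level and the mean level of the
#' voxel's in-lesion neighbours.
#'
#' @inheritParams glcm_matrix
#' @return Data frame with columns `level`, `n`, `s` (one row per level slot).
#' @export
ngtdm_matrix <- function(levels, n_levels) {
  d <- dim(levels)
  nsum <- array(0, dim = d)
  ncnt <- array(0L, dim = d)
  offs <- all_offsets_3d()
  for (r in seq_len(nrow(offs))) {
    nb <- shift_levels(levels, offs[r, ])
    has <- !is.na(nb)
    nsum[has] <- nsum[has] + nb[has]
    ncnt <- ncnt + has
  }
  ok <- !is.na(levels) & ncnt > 0L
  g <- levels[ok]
  diffs <- abs(g - nsum[ok] / ncnt[ok])
  data.frame(
    level = seq_len(n_levels),
    n = tabulate(g, nbins = n_levels),
    s = vapply(seq_len(n_levels), function(i) sum(diffs[g == i]), numeric(1))
  )
}
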