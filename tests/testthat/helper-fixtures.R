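# Fixtures built in code: digital balls, uniform lesions, random discretised
# regions, and independent brute-force oracles for every texture matrix
# family plus an explicit ANOVA-table ICC oracle. The oracles are naive
# loop-based enumerations, deliberately independent of the vectorised
# implementations they check.

ball_mask <- function(radius_vox, spacing = c(1, 1, 1), margin = 3L) {
  d <- rep(2L * ceiling(radius_vox) + 2L * margin + 1L, 3L)
  ctr <- (d + 1) / 2
  idx <- arrayInd(seq_len(prod(d)), d)
  sup <- array(sqrt(rowSums(sweep(idx, 2, ctr)^2)) <= radius_vox, dim = d)
  lesion_mask(sup, spacing)
}

uniform_lesion <- function(value = 4, nvox_side = 4L, spacing = c(1, 1, 1)) {
  d <- rep(nvox_side + 4L, 3L)
  sup <- array(FALSE, dim = d)
  sup[3:(2 + nvox_side), 3:(2 + nvox_side), 3:(2 + nvox_side)] <- TRUE
  img <- image_volume(array(value, dim = d) * 0 + value, spacing)
  list(image = img, mask = lesion_mask(sup, spacing))
}

# Random discretised region: levels array with NA outside a random voxel
# subset of a small grid (<= max_vox in-mask voxels, levels 1..n_levels).
random_levels <- function(max_vox = 100L, dims = c(5L, 5L, 4L), n_levels = 4L) {
  n <- prod(dims)
  k <- min(max_vox, sample(seq(5L, n - 1L), 1))
  sel <- sample.int(n, k)
  lev <- array(NA_integer_, dim = dims)
  lev[sel] <- sample.int(n_levels, k, replace = TRUE)
  # re-index occupied levels contiguously from 1, as discretise() guarantees
  used <- sort(unique(lev[!is.na(lev)]))
  lev[!is.na(lev)] <- match(lev[!is.na(lev)], used)
  list(levels = lev, n_levels = length(used))
}

neighbour_offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
neighbour_offsets <- neighbour_offsets[rowSums(abs(neighbour_offsets)) > 0, ]

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

oracle_glcm <- function(lev, ng) {
  d <- dim(lev)
  P <- matrix(0, ng, ng)
  for (v in which(!is.na(lev))) {
    p <- arrayInd(v, d)
    for (r in seq_len(nrow(neighbour_offsets))) {
      q <- p + neighbour_offsets[r, ]
      if (in_grid(q, d) && !is.na(lev[q[1], q[2], q[3]])) {
        P[lev[v], lev[q[1], q[2], q[3]]] <- P[lev[v], lev[q[1], q[2], q[3]]] + 1
      }
    }
  }
  P
}

oracle_glrlm <- function(lev, ng) {
  d <- dim(lev)
  dirs <- unique(rbind(neighbour_offsets))
  # keep one direction per +/- pair
  keep <- apply(dirs, 1, function(o) {
    o[3] > 0 || (o[3] == 0 && o[2] > 0) || (o[3] == 0 && o[2] == 0 && o[1] > 0)
  })
  dirs <- dirs[keep, , drop = FALSE]
  maxlen <- max(d)
  P <- matrix(0, ng, maxlen)
  for (r in seq_len(nrow(dirs))) {
    o <- dirs[r, ]
    for (v in which(!is.na(lev))) {
      p <- arrayInd(v, d)
      prev <- p - o
      # run starts where the predecessor is absent or a different level
      if (in_grid(prev, d) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
          lev[prev[1], prev[2], prev[3]] == lev[v]) {
        next
      }
      len <- 1L
      q <- p + o
      while (in_grid(q, d) && !is.na(lev[q[1], q[2], q[3]]) &&
             lev[q[1], q[2], q[3]] == lev[v]) {
        len <- len + 1L
        q <- q + o
      }
      P[lev[v], len] <- P[lev[v], len] + 1
    }
  }
  P[, seq_len(max(which(colSums(P) > 0))), drop = FALSE]
}

oracle_glszm <- function(lev, ng) {
  d <- dim(lev)
  visited <- array(FALSE, dim = d)
  zones <- list()
  for (v in which(!is.na(lev))) {
    if (visited[v]) next
    g <- lev[v]
    stack <- list(arrayInd(v, d))
    visited[v] <- TRUE
    size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(neighbour_offsets))) {
        q <- p + neighbour_offsets[r, ]
        if (in_grid(q, d) && !visited[q[1], q[2], q[3]] &&
            !is.na(lev[q[1], q[2], q[3]]) && lev[q[1], q[2], q[3]] == g) {
          visited[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  maxs <- max(vapply(zones, `[`, numeric(1), 2))
  P <- matrix(0, ng, maxs)
  for (z in zones) P[z[1], z[2]] <- P[z[1], z[2]] + 1
  P
}

oracle_gldm <- function(lev, ng, alpha = 0) {
  d <- dim(lev)
  rows <- list()
  for (v in which(!is.na(lev))) {
    p <- arrayInd(v, d)
    dep <- 1L
    for (r in seq_len(nrow(neighbour_offsets))) {
      q <- p + neighbour_offsets[r, ]
      if (in_grid(q, d) && !is.na(lev[q[1], q[2], q[3]]) &&
          abs(lev[q[1], q[2], q[3]] - lev[v]) <= alpha) {
        dep <- dep + 1L
      }
    }
    rows[[length(rows) + 1]] <- c(lev[v], dep)
  }
  maxd <- max(vapply(rows, `[`, numeric(1), 2))
  P <- matrix(0, ng, maxd)
  for (x in rows) P[x[1], x[2]] <- P[x[1], x[2]] + 1
  P
}

oracle_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  n_i <- rep(0, ng)
  s_i <- rep(0, ng)
  for (v in which(!is.na(lev))) {
    p <- arrayInd(v, d)
    nb <- c()
    for (r in seq_len(nrow(neighbour_offsets))) {
      q <- p + neighbour_offsets[r, ]
      if (in_grid(q, d) && !is.na(lev[q[1], q[2], q[3]])) {
        nb <- c(nb, lev[q[1], q[2], q[3]])
      }
    }
    if (length(nb)) {
      n_i[lev[v]] <- n_i[lev[v]] + 1
      s_i[lev[v]] <- s_i[lev[v]] + abs(lev[v] - mean(nb))
    }
  }
  data.frame(level = seq_len(ng), n = n_i, s = s_i)
}

# Explicit two-way ANOVA-table ICC oracle: plain double loops over the
# n x 2 layout, no matrix shortcuts.
oracle_icc_a1 <- function(y1, y2) {
  n <- length(y1)
  k <- 2
  y <- cbind(y1, y2)
  grand <- sum(y) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(y[i, ]) - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(y[, j]) - grand)^2
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (y[i, j] - grand)^2
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  unname((msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)))
}

# Spearman oracle: rank both vectors (average ranks for ties), then Pearson.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

make_gradient_lesion <- function(seed = 1L, side = 5L) {
  set.seed(seed)
  d <- rep(side + 4L, 3L)
  vals <- array(stats::runif(prod(d), 3, 8), dim = d)
  sup <- array(FALSE, dim = d)
  sup[3:(2 + side), 3:(2 + side), 3:(2 + side)] <- TRUE
  list(image = image_volume(vals, c(1, 1, 1)),
       mask = lesion_mask(sup, c(1, 1, 1)))
}
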