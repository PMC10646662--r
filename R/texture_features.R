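# Feature formulas for the radiomics catalogue. Definitions follow the
# widely used open-source radiomics tooling whose catalogue closely aligns
# with the IBSI reference (with that tooling's documented divergences, e.g.
# kurtosis without the -3 offset); texture features are computed on
# direction-merged matrices. Degenerate denominators on uniform regions
# return 0 for contrast-like features and 1 for uniformity/correlation-like
# features (Coarseness is capped at 1e6, the reference tooling's constant).

.feps <- 2.220446e-16

firstorder_features <- function(vals, voxel_volume_mm3, bin_width = 0.2) {
  n <- length(vals)
  mu <- mean(vals)
  m2 <- mean((vals - mu)^2)
  m3 <- mean((vals - mu)^3)
  m4 <- mean((vals - mu)^4)
  qs <- stats::quantile(vals, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  robust <- vals[vals >= qs[1] & vals <= qs[5]]
  # histogram with fixed bin width for entropy/uniformity
  base <- floor(min(vals) / bin_width)
  lev <- floor(vals / bin_width) - base + 1
  p <- tabulate(lev) / n
  p <- p[p > 0]
  list(
    Energy = sum(vals^2),
    TotalEnergy = voxel_volume_mm3 * sum(vals^2),
    Entropy = -sum(p * log2(p + .feps)),
    Minimum = min(vals),
    `10Percentile` = qs[1],
    `90Percentile` = qs[5],
    Maximum = max(vals),
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(vals) - min(vals),
    MeanAbsoluteDeviation = mean(abs(vals - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(vals^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}

glcm_features <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  if (tot == 0) {
    # single-voxel region: no co-occurrences at all
    P <- matrix(1, 1, 1)
    ng <- 1L
    tot <- 1
  }
  p <- P / tot
  i <- row(p)
  j <- col(p)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(seq_len(ng) * px)
  muy <- sum(seq_len(ng) * py)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # diagonal (difference) and cross-diagonal (sum) probabilities
  kdiff <- 0:(ng - 1)
  pxmy <- vapply(kdiff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  ksum <- 2:(2 * ng)
  pxpy <- vapply(ksum, function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum(kdiff * pxmy)
  hx <- -sum(px[px > 0] * log2(px[px > 0] + .feps))
  hy <- -sum(py[py > 0] * log2(py[py > 0] + .feps))
  hxy <- -sum(p[p > 0] * log2(p[p > 0] + .feps))
  pxy_outer <- outer(px, py)
  nz <- p > 0
  hxy1 <- -sum(p[nz] * log2(pxy_outer[nz] + .feps))
  nz2 <- pxy_outer > 0
  hxy2 <- -sum(pxy_outer[nz2] * log2(pxy_outer[nz2] + .feps))
  corr <- if (sigx * sigy > 0) {
    (sum(p * i * j) - mux * muy) / (sigx * sigy)
  } else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  # MCC: second largest eigenvalue of the transition-style matrix Q
  mcc <- if (ng == 1L) 1 else {
    denom <- outer(px, py)
    denom[denom == 0] <- .feps
    # Q[a,b] = sum_k p(a,k) p(b,k) / (px(a) py(k))
    W <- sweep(p, 2, pmax(py, .feps), `/`)
    Q <- sweep(p %*% t(W), 1, pmax(px, .feps), `/`)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  offdiag <- i != j
  list(
    Autocorrelation = sum(p * i * j),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxmy[pxmy > 0] * log2(pxmy[pxmy > 0] + .feps)),
    DifferenceVariance = sum((kdiff - da)^2 * pxmy),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    InverseVariance = sum(p[offdiag] / (i[offdiag] - j[offdiag])^2),
    MaximumProbability = max(p),
    SumAverage = sum(ksum * pxpy),
    SumEntropy = -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0] + .feps)),
    SumSquares = sum((i - mux)^2 * p),
    MCC = mcc
  )
}

glrlm_features <- function(P, n_voxels, n_directions = 13) {
  nr <- sum(P)
  p <- P / nr
  i <- row(p)
  j <- col(p)
  pg <- rowSums(p)
  pr <- colSums(p)
  mui <- sum(row(p)[, 1] * pg)
  muj <- sum(col(p)[1, ] * pr)
  list(
    ShortRunEmphasis = sum(p / j^2),
    LongRunEmphasis = sum(p * j^2),
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(pg^2),
    RunLengthNonUniformity = sum(colSums(P)^2) / nr,
    RunLengthNonUniformityNormalized = sum(pr^2),
    RunPercentage = nr / (n_voxels * n_directions),
    GrayLevelVariance = sum(p * (i - mui)^2),
    RunVariance = sum(p * (j - muj)^2),
    RunEntropy = -sum(p[p > 0] * log2(p[p > 0] + .feps)),
    LowGrayLevelRunEmphasis = sum(p / i^2),
    HighGrayLevelRunEmphasis = sum(p * i^2),
    ShortRunLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    ShortRunHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    LongRunLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LongRunHighGrayLevelEmphasis = sum(p * i^2 * j^2)
  )
}

glszm_features <- function(P, n_voxels) {
  nz <- sum(P)
  p <- P / nz
  i <- row(p)
  j <- col(p)
  pg <- rowSums(p)
  ps <- colSums(p)
  mui <- sum(row(p)[, 1] * pg)
  muj <- sum(col(p)[1, ] * ps)
  list(
    SmallAreaEmphasis = sum(p / j^2),
    LargeAreaEmphasis = sum(p * j^2),
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(pg^2),
    SizeZoneNonUniformity = sum(colSums(P)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(ps^2),
    ZonePercentage = nz / n_voxels,
    GrayLevelVariance = sum(p * (i - mui)^2),
    ZoneVariance = sum(p * (j - muj)^2),
    ZoneEntropy = -sum(p[p > 0] * log2(p[p > 0] + .feps)),
    LowGrayLevelZoneEmphasis = sum(p / i^2),
    HighGrayLevelZoneEmphasis = sum(p * i^2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    SmallAreaHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    LargeAreaLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LargeAreaHighGrayLevelEmphasis = sum(p * i^2 * j^2)
  )
}

gldm_features <- function(P) {
  nz <- sum(P)
  p <- P / nz
  i <- row(p)
  j <- col(p)
  pg <- rowSums(p)
  pd <- colSums(p)
  mui <- sum(row(p)[, 1] * pg)
  muj <- sum(col(p)[1, ] * pd)
  list(
    SmallDependenceEmphasis = sum(p / j^2),
    LargeDependenceEmphasis = sum(p * j^2),
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(pd^2),
    GrayLevelVariance = sum(p * (i - mui)^2),
    DependenceVariance = sum(p * (j - muj)^2),
    DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0] + .feps)),
    LowGrayLevelEmphasis = sum(p / i^2),
    HighGrayLevelEmphasis = sum(p * i^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    LargeDependenceLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LargeDependenceHighGrayLevelEmphasis = sum(p * i^2 * j^2)
  )
}

ngtdm_features <- function(tab) {
  present <- tab$n > 0
  N <- sum(tab$n)
  if (N == 0) {
    # no voxel has a valid neighbourhood (e.g. a single-voxel region)
    return(list(Coarseness = 1e6, Contrast = 0, Busyness = 0,
                Complexity = 0, Strength = 0))
  }
  p <- tab$n / N
  s <- tab$s
  lev <- tab$level
  ngp <- sum(present)
  ip <- which(present)
  coars_den <- sum(p * s)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  if (ngp <= 1L) {
    return(list(Coarseness = coarseness, Contrast = 0, Busyness = 0,
                Complexity = 0, Strength = 0))
  }
  pi_ <- p[ip]
  si <- s[ip]
  li <- lev[ip]
  dd <- outer(li, li, `-`)
  contrast <- (sum(outer(pi_, pi_) * dd^2) / (ngp * (ngp - 1))) * (sum(si) / N)
  # denominator is the full double sum over present-level pairs
  bus_den <- sum(abs(outer(li * pi_, li * pi_, `-`)))
  busyness <- if (bus_den > 0) coars_den / bus_den else 0
  psum <- outer(pi_, pi_, `+`)
  complexity <- sum(abs(dd) * (outer(pi_ * si, pi_ * si, `+`) / psum)) / N
  strength_den <- sum(s)
  strength <- if (strength_den > 0) sum(psum * dd^2) / strength_den else 0
  list(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
       Complexity = complexity, Strength = strength)
}
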