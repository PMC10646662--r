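# Shape features from a triangulated surface mesh of the binary mask.
# The mesh is built by marching tetrahedra on the 0.5-level of the (zero
# padded) mask, with triangle vertices at the midpoints of edges crossing
# the surface; mesh volume comes from the divergence theorem. Axis lengths
# come from a principal-component analysis of the physical voxel-centre
# coordinates.

# Split of the unit cube (corner indices 0..7 in binary x + 2y + 4z order)
# into six tetrahedra sharing the main diagonal 0-7.
.tet_decomposition <- matrix(c(
  0, 1, 3, 7,
  0, 1, 5, 7,
  0, 2, 3, 7,
  0, 2, 6, 7,
  0, 4, 5, 7,
  0, 4, 6, 7
) + 1, ncol = 4, byrow = TRUE)

.cube_corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))

# Triangulate the 0.5-level iso-surface of the mask indicator by marching
# tetrahedra with linear interpolation of edge crossings. The indicator is
# first smoothed with a separable (1/4, 1/2, 1/4) kernel so the faceted
# staircase of the raw binary surface is relaxed towards the underlying
# smooth boundary (surface area of digitised ellipsoids then converges to
# the analytic value); masks too small to survive smoothing fall back to the
# raw binary field with midpoint vertices. Returns a matrix of vertex
# coordinates in physical mm (consecutive row triples form one outward
# oriented triangle).
mask_surface_mesh <- function(support, spacing_mm) {
  d <- dim(support)
  pad <- array(0, dim = d + 4L)
  pad[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- as.numeric(support)
  field <- gaussian_smooth_kernel(pad, c(0.25, 0.5, 0.25))
  if (max(field) <= 0.5) field <- pad   # tiny mask: raw binary field
  dp <- dim(field)
  inside <- field > 0.5
  # cells with mixed corners
  occ <- array(0L, dim = dp - 1L)
  for (c8 in seq_len(8)) {
    cc <- .cube_corners[c8, ]
    occ <- occ + inside[(1 + cc[1]):(dp[1] - 1 + cc[1]),
                        (1 + cc[2]):(dp[2] - 1 + cc[2]),
                        (1 + cc[3]):(dp[3] - 1 + cc[3])]
  }
  mixed <- which(occ > 0L & occ < 8L)
  if (length(mixed) == 0L) {
    return(matrix(numeric(0), ncol = 3))
  }
  cells <- arrayInd(mixed, dp - 1L)
  tris <- vector("list", 4096)
  nt <- 0L
  add_tri <- function(v1, v2, v3, inside_pt) {
    nrm <- crossprod3(v2 - v1, v3 - v1)
    if (sum(nrm * (v1 - inside_pt)) < 0) {
      tmp <- v2; v2 <- v3; v3 <- tmp
    }
    nt <<- nt + 1L
    tris[[nt]] <<- rbind(v1, v2, v3)
  }
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    corner_pos <- sweep(.cube_corners, 2, cell, `+`)   # padded voxel idx
    vals <- field[corner_pos]
    inn <- vals > 0.5
    # physical coordinates of corners (centres of the padded grid, shifted
    # back by the two voxels of padding)
    coords <- sweep(corner_pos, 2, 2.5) * rep(spacing_mm, each = 8)
    for (t in seq_len(6)) {
      vidx <- .tet_decomposition[t, ]
      tv <- inn[vidx]
      n_in <- sum(tv)
      if (n_in == 0L || n_in == 4L) next
      tc <- coords[vidx, , drop = FALSE]
      fv <- vals[vidx]
      ins <- which(tv)
      outs <- which(!tv)
      cut <- function(a, b) {
        # linear crossing of the 0.5 level along edge a-b
        w <- (0.5 - fv[a]) / (fv[b] - fv[a])
        tc[a, ] + w * (tc[b, ] - tc[a, ])
      }
      inside_pt <- colMeans(tc[ins, , drop = FALSE])
      if (n_in == 1L) {
        a <- ins
        add_tri(cut(a, outs[1]), cut(a, outs[2]), cut(a, outs[3]), tc[a, ])
      } else if (n_in == 3L) {
        a <- outs
        add_tri(cut(ins[1], a), cut(ins[2], a), cut(ins[3], a), inside_pt)
      } else {
        p11 <- cut(ins[1], outs[1]); p12 <- cut(ins[1], outs[2])
        p21 <- cut(ins[2], outs[1]); p22 <- cut(ins[2], outs[2])
        add_tri(p11, p12, p21, inside_pt)
        add_tri(p21, p12, p22, inside_pt)
      }
    }
  }
  do.call(rbind, tris[seq_len(nt)])
}

gaussian_smooth_kernel <- function(arr, k) {
  for (ax in 1:3) arr <- convolve_axis(arr, k, ax, pad = "zero")
  arr
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

mesh_volume_area <- function(verts) {
  if (nrow(verts) == 0L) return(c(volume = 0, area = 0))
  i1 <- seq(1, nrow(verts), by = 3)
  v1 <- verts[i1, , drop = FALSE]
  v2 <- verts[i1 + 1, , drop = FALSE]
  v3 <- verts[i1 + 2, , drop = FALSE]
  cr <- cbind(
    (v2[, 2] - v1[, 2]) * (v3[, 3] - v1[, 3]) - (v2[, 3] - v1[, 3]) * (v3[, 2] - v1[, 2]),
    (v2[, 3] - v1[, 3]) * (v3[, 1] - v1[, 1]) - (v2[, 1] - v1[, 1]) * (v3[, 3] - v1[, 3]),
    (v2[, 1] - v1[, 1]) * (v3[, 2] - v1[, 2]) - (v2[, 2] - v1[, 2]) * (v3[, 1] - v1[, 1])
  )
  area <- sum(sqrt(rowSums(cr^2))) / 2
  volume <- abs(sum(v1[, 1] * cr[, 1] + v1[, 2] * cr[, 2] + v1[, 3] * cr[, 3])) / 6
  c(volume = volume, area = area)
}

max_pairwise_distance <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  # reduce to extreme points per direction grid to keep O(n^2) affordable
  if (nrow(pts) > 3000L) {
    keep <- unique(unlist(lapply(1:3, function(ax) {
      c(which.min(pts[, ax]), which.max(pts[, ax]))
    })))
    # coarse subsample plus axis extremes
    keep <- unique(c(keep, seq(1, nrow(pts), length.out = 3000L)))
    pts <- pts[keep, , drop = FALSE]
  }
  d2 <- as.matrix(stats::dist(pts))
  max(d2)
}

#' Shape features of a lesion mask
#'
#' Fourteen mesh- and PCA-based descriptors of the 3-D lesion geometry:
#' mesh volume and voxel-count volume (mL converted to mm^3 internally),
#' surface area, surface-to-volume ratio, sphericity, the maximum 3-D
#' diameter and the three maximum in-plane 2-D diameters, the three
#' principal axis lengths, elongation and flatness. Shape is computed on
#' the (unfiltered) mask geometry only and is therefore identical across
#' image filters.
#'
#' @param mask a non-empty `lesion_mask`.
#' @return Named list of 14 shape features (lengths in mm, volumes in mm^3).
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"), any(mask$support))
  sp <- mask$spacing_mm
  verts <- mask_surface_mesh(mask$support, sp)
  va <- mesh_volume_area(verts)
  vol_mesh <- va["volume"]
  area <- va["area"]
  nvox <- sum(mask$support)
  idx <- arrayInd(which(mask$support), dim(mask$support))
  coords <- sweep(idx, 2, 0.5) * rep(sp, each = nrow(idx))
  if (nrow(coords) > 1L) {
    ev <- eigen(stats::cov(coords), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  uverts <- unique(round(verts, 6))
  max3d <- max_pairwise_distance(uverts)
  plane_diam <- function(drop_ax) {
    # max in-plane distance among vertices sharing the dropped coordinate
    key <- uverts[, drop_ax]
    groups <- split(seq_len(nrow(uverts)), key)
    best <- 0
    for (g in groups) {
      if (length(g) < 2L) next
      best <- max(best, max_pairwise_distance(uverts[g, -drop_ax, drop = FALSE]))
    }
    best
  }
  list(
    MeshVolume = unname(vol_mesh),
    VoxelVolume = nvox * prod(sp),
    SurfaceArea = unname(area),
    SurfaceVolumeRatio = unname(if (vol_mesh > 0) area / vol_mesh else 0),
    Sphericity = unname(if (area > 0) (36 * pi * vol_mesh^2)^(1 / 3) / area else 1),
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = plane_diam(3),   # x-y plane
    Maximum2DDiameterColumn = plane_diam(2),  # x-z plane
    Maximum2DDiameterRow = plane_diam(1),     # y-z plane
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  )
}
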