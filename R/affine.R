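# Geometry conventions: world space is RAS+ millimetres (x right, y anterior,
# z superior); voxel indices are 0-based in the affine algebra (converted from
# R's 1-based arrays at the boundary); a voxel is represented by its center.

#' Voxel spacing implied by an affine
#'
#' @param affine 4x4 voxel-index-to-world matrix.
#' @return Numeric length-3 vector of mm per voxel along each array axis.
#' @keywords internal
affine_spacing <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Map 0-based voxel indices to world coordinates
#'
#' @param affine 4x4 affine.
#' @param ijk n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world mm coordinates.
#' @keywords internal
world_from_voxel <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  p <- cbind(ijk, 1) %*% t(affine)
  p[, 1:3, drop = FALSE]
}

#' Map world coordinates to 0-based voxel indices
#' @inheritParams world_from_voxel
#' @param xyz n x 3 matrix of world mm coordinates.
#' @keywords internal
voxel_from_world <- function(affine, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  p <- cbind(xyz, 1) %*% t(solve(affine))
  p[, 1:3, drop = FALSE]
}

# World coordinates of all TRUE voxels' centers in a mask.
mask_world_coords <- function(mask, affine) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), ncol = 3))
  world_from_voxel(affine, idx - 1)
}

#' Trilinear interpolation of a 3D field at world points
#'
#' Coordinates falling outside the grid are clamped to the boundary, so the
#' returned value is the nearest in-grid interpolant.
#'
#' @param field 3D numeric array defined on voxel centers.
#' @param affine 4x4 voxel-to-world affine of the grid.
#' @param xyz n x 3 matrix of world points (mm).
#' @return Numeric vector of interpolated values.
#' @keywords internal
interp_trilinear <- function(field, affine, xyz) {
  dm <- dim(field)
  v <- voxel_from_world(affine, xyz)
  # clamp continuous coordinates into [0, dim-1]
  for (a in 1:3) v[, a] <- pmin(pmax(v[, a], 0), dm[a] - 1)
  lo <- floor(v)
  for (a in 1:3) lo[, a] <- pmin(lo[, a], dm[a] - 2)
  lo[lo < 0] <- 0
  fr <- v - lo
  i0 <- lo[, 1]; j0 <- lo[, 2]; k0 <- lo[, 3]
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  nx <- dm[1]; nxy <- dm[1] * dm[2]
  at <- function(di, dj, dk) {
    field[1 + (i0 + di) + (j0 + dj) * nx + (k0 + dk) * nxy]
  }
  c000 <- at(0, 0, 0); c100 <- at(1, 0, 0)
  c010 <- at(0, 1, 0); c110 <- at(1, 1, 0)
  c001 <- at(0, 0, 1); c101 <- at(1, 0, 1)
  c011 <- at(0, 1, 1); c111 <- at(1, 1, 1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# Central-difference gradient of a field at world points, in world units.
# h is the finite-difference half-step in mm.
field_gradient <- function(field, affine, xyz, h = 0.5) {
  xyz <- matrix(xyz, ncol = 3)
  g <- matrix(0, nrow(xyz), 3)
  for (a in 1:3) {
    e <- c(0, 0, 0); e[a] <- h
    hi <- interp_trilinear(field, affine, sweep(xyz, 2, e, "+"))
    lo <- interp_trilinear(field, affine, sweep(xyz, 2, e, "-"))
    g[, a] <- (hi - lo) / (2 * h)
  }
  g
}

# Nearest-voxel boolean lookup of a mask at world points; points outside the
# grid return FALSE.
mask_lookup <- function(mask, affine, xyz) {
  dm <- dim(mask)
  v <- round(voxel_from_world(affine, xyz))
  ok <- v[, 1] >= 0 & v[, 1] < dm[1] &
        v[, 2] >= 0 & v[, 2] < dm[2] &
        v[, 3] >= 0 & v[, 3] < dm[3]
  out <- logical(nrow(v))
  if (any(ok)) {
    idx <- 1 + v[ok, 1] + v[ok, 2] * dm[1] + v[ok, 3] * dm[1] * dm[2]
    out[ok] <- mask[idx]
  }
  out
}

# Unit vector helper
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector cannot be normalized")
  v / n
}
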