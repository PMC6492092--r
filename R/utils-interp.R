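# Trilinear interpolation, warping operators and deformation-field helpers.
#
# Displacement fields are stored as 4D arrays dim = c(nx, ny, nz, 3) holding
# millimetre displacements along (SI, RL, AP). A field `d` warps a volume by
# pull-back sampling: warp(v, d)(p) = v(p + d(p)/spacing) in voxel units.

#' Voxel-centre coordinate grid
#'
#' @param dim integer length-3 grid size
#' @return matrix `prod(dim) x 3` of 1-based voxel coordinates, column-major
#' @keywords internal
voxel_grid <- function(dim) {
  cbind(
    rep.int(seq_len(dim[1]), dim[2] * dim[3]),
    rep.int(rep(seq_len(dim[2]), each = dim[1]), dim[3]),
    rep(seq_len(dim[3]), each = dim[1] * dim[2])
  )
}

#' Sparse trilinear interpolation operator
#'
#' Builds the `n_points x prod(dim)` sparse matrix `M` such that `M %*%
#' as.vector(vol)` trilinearly samples `vol` at `coords` (1-based voxel
#' units). Coordinates are clamped to the grid. The transpose of `M` is the
#' exact adjoint (splatting) of the interpolation, which is what the
#' motion-compensated reconstruction relies on.
#'
#' @param dim grid size (length 3)
#' @param coords numeric matrix `n x 3` of sample positions (voxel units)
#' @return a `dgCMatrix`
#' @keywords internal
interp_matrix <- function(dim, coords) {
  n <- nrow(coords)
  cx <- pmin(pmax(coords[, 1], 1), dim[1])
  cy <- pmin(pmax(coords[, 2], 1), dim[2])
  cz <- pmin(pmax(coords[, 3], 1), dim[3])
  x0 <- pmin(floor(cx), dim[1] - 1L); fx <- cx - x0
  y0 <- pmin(floor(cy), dim[2] - 1L); fy <- cy - y0
  z0 <- pmin(floor(cz), dim[3] - 1L); fz <- cz - z0
  if (dim[1] == 1L) { x0 <- rep(1, n); fx <- rep(0, n) }
  if (dim[2] == 1L) { y0 <- rep(1, n); fy <- rep(0, n) }
  if (dim[3] == 1L) { z0 <- rep(1, n); fz <- rep(0, n) }
  ii <- jj <- xx <- vector("list", 8)
  k <- 1
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    idx <- (x0 + dx) + dim[1] * (y0 + dy - 1) + dim[1] * dim[2] * (z0 + dz - 1)
    keep <- w > 0
    ii[[k]] <- which(keep); jj[[k]] <- idx[keep]; xx[[k]] <- w[keep]
    k <- k + 1
  }
  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n, prod(dim))
  )
}

#' Apply a sparse operator to a complex vector
#' @keywords internal
apply_complex <- function(M, v) {
  if (is.complex(v)) {
    as.vector(M %*% Re(v)) + 1i * as.vector(M %*% Im(v))
  } else {
    as.vector(M %*% v)
  }
}

#' Warp operator for a displacement field
#'
#' Returns the sparse matrix implementing pull-back warping by `field` (mm):
#' the warped volume at voxel p equals the input sampled at p + d(p)/spacing.
#' @param field displacement array `c(dim, 3)` in mm
#' @param spacing voxel size mm (scalar or length 3)
#' @keywords internal
warp_matrix <- function(field, spacing) {
  d <- dim(field)[1:3]
  spacing <- rep(spacing, length.out = 3)
  g <- voxel_grid(d)
  g[, 1] <- g[, 1] + as.vector(field[, , , 1]) / spacing[1]
  g[, 2] <- g[, 2] + as.vector(field[, , , 2]) / spacing[2]
  g[, 3] <- g[, 3] + as.vector(field[, , , 3]) / spacing[3]
  interp_matrix(d, g)
}

#' Warp a volume by a displacement field
#'
#' @param vol 3D array (numeric or complex)
#' @param field displacement array `c(dim(vol), 3)` in mm
#' @param spacing voxel size mm
#' @return warped volume, same type and dimensions
#' @export
warp_volume <- function(vol, field, spacing) {
  M <- warp_matrix(field, spacing)
  array(apply_complex(M, as.vector(vol)), dim(vol))
}

#' Minimum Jacobian determinant of the transform identity + field
#'
#' Finite-difference Jacobian over the interior grid; a positive minimum
#' certifies local invertibility of the deformation.
#' @param field displacement array `c(dim, 3)` in mm
#' @param spacing voxel size mm
#' @return scalar minimum determinant
#' @export
jacobian_min <- function(field, spacing) {
  spacing <- rep(spacing, length.out = 3)
  d <- dim(field)[1:3]
  grad <- function(a, axis) {
    n <- d[axis]
    if (n < 3) return(array(0, d))
    idx_p <- c(2:n, n); idx_m <- c(1, 1:(n - 1))
    ap <- switch(axis, a[idx_p, , ], a[, idx_p, ], a[, , idx_p])
    am <- switch(axis, a[idx_m, , ], a[, idx_m, ], a[, , idx_m])
    step <- array(2 * spacing[axis], d)
    edge1 <- switch(axis, slice.index(a, 1) == 1, slice.index(a, 2) == 1,
                    slice.index(a, 3) == 1)
    edgeN <- switch(axis, slice.index(a, 1) == n, slice.index(a, 2) == n,
                    slice.index(a, 3) == n)
    step[edge1 | edgeN] <- spacing[axis]
    (ap - am) / step
  }
  J11 <- 1 + grad(field[, , , 1], 1); J12 <- grad(field[, , , 1], 2)
  J13 <- grad(field[, , , 1], 3)
  J21 <- grad(field[, , , 2], 1); J22 <- 1 + grad(field[, , , 2], 2)
  J23 <- grad(field[, , , 2], 3)
  J31 <- grad(field[, , , 3], 1); J32 <- grad(field[, , , 3], 2)
  J33 <- 1 + grad(field[, , , 3], 3)
  det <- J11 * (J22 * J33 - J23 * J32) -
         J12 * (J21 * J33 - J23 * J31) +
         J13 * (J21 * J32 - J22 * J31)
  min(det)
}
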