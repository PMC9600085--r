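#' Regular 3D image grid
#'
#' A `grid3d` describes the sampling lattice shared by CT volumes, dose
#' volumes, masks and deformation fields: voxel counts, voxel spacing in mm,
#' the physical position of the *center* of voxel (0,0,0), and an axis-aligned
#' direction matrix. Voxel indexing is 0-based and the physical point of a
#' voxel is its center, so voxel (i,j,k) sits at
#' `origin + direction %*% (spacing * c(i,j,k))`.
#'
#' Only axis-aligned orientations (identity or signed permutation matrices)
#' are supported; oblique direction matrices are rejected.
#'
#' @param size integer vector of length 3, voxels per axis.
#' @param spacing numeric vector of length 3, mm per voxel, all > 0.
#' @param origin numeric vector of length 3, mm; center of voxel (0,0,0).
#' @param direction 3x3 axis-aligned direction-cosine matrix.
#' @return An object of class `grid3d`.
#' @examples
#' g <- grid3d(c(128, 128, 64), c(2, 2, 2.5))
#' grid_extent_mm(g)
#' @export
grid3d <- function(size, spacing, origin = c(0, 0, 0), direction = diag(3)) {
  size <- as.integer(size)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  stopifnot(length(size) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(size < 1L)) stop("grid size must be positive along every axis")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("grid spacing must be positive along every axis")
  }
  if (!all(dim(direction) == c(3L, 3L))) stop("direction must be a 3x3 matrix")
  if (!is_axis_aligned(direction)) {
    stop("oblique direction matrices are not supported; ",
         "only identity or signed-permutation orientations")
  }
  structure(list(size = size, spacing = spacing, origin = origin,
                 direction = direction),
            class = "grid3d")
}

# TRUE iff each row/column has exactly one entry of magnitude 1 (tol 1e-6)
is_axis_aligned <- function(direction) {
  d <- abs(direction)
  ok_entries <- all(d < 1e-6 | abs(d - 1) < 1e-6)
  ok_entries && all(colSums(d > 0.5) == 1) && all(rowSums(d > 0.5) == 1)
}

#' @export
print.grid3d <- function(x, ...) {
  cat("grid3d:", paste(x$size, collapse = " x "), "voxels, spacing",
      paste(format(x$spacing), collapse = " x "), "mm\n")
  cat("  origin (mm):", paste(format(x$origin), collapse = ", "), "\n")
  if (!identical(unname(x$direction), diag(3))) {
    cat("  direction: axis-aligned, non-identity\n")
  }
  invisible(x)
}

#' Physical extent of a grid
#'
#' Returns the per-axis physical length in mm (`size * spacing`).
#' @param grid a [grid3d()].
#' @return numeric length-3 vector, mm.
#' @export
grid_extent_mm <- function(grid) grid$size * grid$spacing

#' Number of voxels in a grid
#' @param grid a [grid3d()].
#' @return integer voxel count.
#' @export
grid_nvoxel <- function(grid) prod(grid$size)

#' Volume of one voxel in cubic centimetres
#' @param grid a [grid3d()].
#' @return voxel volume in cc.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

#' Test whether two grids are aligned
#'
#' Two grids are aligned iff size, spacing, origin and direction agree within
#' `tol` (mm for lengths). Alignment at a fixed tolerance is symmetric; it is
#' transitive in practice because grid metadata is stored exactly.
#'
#' @param a,b [grid3d()] objects.
#' @param tol tolerance in mm (default 1e-6).
#' @return logical.
#' @export
grids_aligned <- function(a, b, tol = 1e-6) {
  all(a$size == b$size) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$direction - b$direction) <= tol)
}

stop_if_misaligned <- function(a, b, what = "volumes") {
  if (!grids_aligned(a, b)) stop(what, " are not on aligned grids")
  invisible(TRUE)
}

#' Physical coordinates of voxel centers
#'
#' Converts 0-based voxel indices to physical mm coordinates.
#' @param grid a [grid3d()].
#' @param ijk n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of physical points, mm.
#' @export
voxel_to_physical <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  mm <- ijk * matrix(grid$spacing, nrow(ijk), 3, byrow = TRUE)
  t(grid$direction %*% t(mm)) +
    matrix(grid$origin, nrow(ijk), 3, byrow = TRUE)
}

# internal fast paths assuming identity-direction grids
vox2phys <- function(grid, ijk) {
  sweep(ijk * matrix(grid$spacing, nrow(ijk), 3, byrow = TRUE),
        2, grid$origin, `+`)
}
phys2vox <- function(grid, xyz) {
  sweep(xyz, 2, grid$origin, `-`) /
    matrix(grid$spacing, nrow(xyz), 3, byrow = TRUE)
}

stop_if_not_identity_direction <- function(grid, what = "this operation") {
  if (max(abs(grid$direction - diag(3))) > 1e-6) {
    stop(what, " requires an identity-direction grid")
  }
  invisible(TRUE)
}

#' Grid centered on the origin of physical space
#'
#' Convenience constructor placing the grid so that its physical center is at
#' (0,0,0) mm — the convention used by the digital head phantom.
#' @param size integer length-3 voxel counts.
#' @param spacing numeric length-3 spacing, mm.
#' @return a [grid3d()].
#' @export
grid3d_centered <- function(size, spacing) {
  size <- as.integer(size)
  spacing <- as.numeric(spacing)
  origin <- -(size - 1) * spacing / 2
  grid3d(size, spacing, origin)
}
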