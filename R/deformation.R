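#' Generate a smooth random deformation field
#'
#' Draws random displacements on a coarse control grid (spacing
#' `control_spacing` mm per axis), interpolates them trilinearly onto the
#' image grid (band-limited smoothness by construction), and scales the
#' field so that the maximum displacement magnitude equals
#' `max_displacement`. The result is deterministic for a fixed seed.
#'
#' These fields are plumbing for contour-similarity metrics, not a model of
#' anatomical deformation: they are not constrained to be diffeomorphic.
#'
#' @param grid a [grid3d()].
#' @param control_spacing control-point spacing in mm; must not be smaller
#'   than the voxel spacing.
#' @param max_displacement maximum displacement magnitude in mm (>= 0).
#' @param seed integer seed.
#' @return a [deformation_field()].
#' @export
generate_deformation <- function(grid, control_spacing = 30,
                                 max_displacement = 5, seed = 1) {
  if (max_displacement < 0) stop("max_displacement must be >= 0")
  if (any(control_spacing < grid$spacing)) {
    stop("control spacing must not be smaller than the voxel spacing")
  }
  if (max_displacement == 0) return(identity_deformation(grid))
  nctrl <- pmax(2L, as.integer(ceiling(grid_extent_mm(grid) /
                                         control_spacing)) + 1L)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  ctrl <- array(stats::rnorm(prod(nctrl) * 3), c(nctrl, 3L))
  # continuous control-grid coordinates of each voxel center
  pts <- grid_center_points(grid)
  rel <- sweep(pts, 2, grid$origin - 0.5 * grid$spacing, `-`)
  cs <- grid_extent_mm(grid) / (nctrl - 1L)
  idx <- rel / matrix(cs, nrow(rel), 3, byrow = TRUE)
  disp <- vapply(1:3, function(a) {
    cpp_sample_volume(as.numeric(ctrl[, , , a]), nctrl, idx, 0L, 0, TRUE)
  }, numeric(nrow(idx)))
  mag <- sqrt(rowSums(disp^2))
  scale <- if (max(mag) > 0) max_displacement / max(mag) else 0
  deformation_field(array(disp * scale, c(grid$size, 3L)), grid)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Warp a volume or mask through a deformation field
#'
#' Pull-back warping: the output value at voxel x is the input sampled at
#' x + displacement(x). The identity field reproduces the input exactly;
#' masks must use nearest interpolation and stay binary. Reads outside the
#' grid return background (-1000 HU for CT, 0 otherwise).
#'
#' @param vol a [volume3d()].
#' @param field a [deformation_field()] aligned to `vol`'s grid.
#' @param interpolation `"nearest"` or `"trilinear"`; masks require nearest.
#' @return warped [volume3d()].
#' @export
apply_deformation <- function(vol, field,
                              interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stop_if_misaligned(vol$grid, field$grid, "volume and deformation field")
  if (vol$kind == "mask" && interpolation != "nearest") {
    stop("binary masks must be warped with nearest interpolation")
  }
  if (field$max_displacement_mm == 0) return(vol)
  g <- vol$grid
  pts <- grid_center_points(g)
  pts <- pts + cbind(as.numeric(field$displacement[, , , 1]),
                     as.numeric(field$displacement[, , , 2]),
                     as.numeric(field$displacement[, , , 3]))
  idx <- phys2vox(g, pts)
  fill <- if (vol$kind == "ct") -1000 else 0
  sampled <- cpp_sample_volume(as.numeric(vol$values), g$size, idx,
                               if (interpolation == "nearest") 1L else 0L,
                               fill, TRUE)
  if (vol$kind == "ct") sampled <- round_hu(sampled)
  volume3d(array(sampled, g$size), g, kind = vol$kind)
}
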