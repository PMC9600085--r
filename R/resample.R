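#' Resample a volume onto a target grid
#'
#' Samples the input volume at the voxel centers of `target`. Voxels of the
#' target that fall outside the source physical extent are filled with
#' -1000 HU (air) for CT volumes and 0 for dose, mask and generic scalar
#' volumes. Masks may only be resampled with nearest-neighbour interpolation
#' (trilinear would break binarity).
#'
#' @param vol a [volume3d()].
#' @param target a [grid3d()] overlapping the source extent.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return a [volume3d()] of the same kind on `target`.
#' @export
resample_to_grid <- function(vol, target,
                             interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (vol$kind == "mask" && interpolation != "nearest") {
    stop("binary masks must be resampled with nearest interpolation")
  }
  stop_if_not_identity_direction(vol$grid, "resampling")
  stop_if_not_identity_direction(target, "resampling")
  if (grids_aligned(vol$grid, target)) return(vol)
  src_lo <- vol$grid$origin - 0.5 * vol$grid$spacing
  src_hi <- vol$grid$origin + (vol$grid$size - 0.5) * vol$grid$spacing
  tgt_lo <- target$origin - 0.5 * target$spacing
  tgt_hi <- target$origin + (target$size - 0.5) * target$spacing
  if (any(tgt_hi < src_lo) || any(tgt_lo > src_hi)) {
    stop("target grid does not overlap the source physical extent")
  }
  fill <- if (vol$kind == "ct") -1000 else 0
  pts <- grid_center_points(target)
  idx <- phys2vox(vol$grid, pts)
  sampled <- cpp_sample_volume(as.numeric(vol$values), vol$grid$size, idx,
                               if (interpolation == "nearest") 1L else 0L,
                               fill, TRUE)
  if (vol$kind == "ct") sampled <- round_hu(sampled)
  volume3d(array(sampled, target$size), target, kind = vol$kind)
}

# physical coordinates of all voxel centers, fastest-varying axis first
grid_center_points <- function(grid) {
  n <- grid$size
  i <- rep.int(seq_len(n[1]) - 1L, n[2] * n[3])
  j <- rep.int(rep(seq_len(n[2]) - 1L, each = n[1]), n[3])
  k <- rep(seq_len(n[3]) - 1L, each = n[1] * n[2])
  cbind(grid$origin[1] + i * grid$spacing[1],
        grid$origin[2] + j * grid$spacing[2],
        grid$origin[3] + k * grid$spacing[3])
}
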