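#' CT, dose, mask and generic scalar volumes
#'
#' A `volume3d` couples a 3D numeric array (indexed `[i+1, j+1, k+1]` for
#' 0-based voxel (i,j,k)) with its [grid3d()]. The `kind` field carries the
#' value semantics:
#' \describe{
#'   \item{`"ct"`}{Hounsfield units, integer-valued, clamped to
#'     \eqn{[-1024, 3071]}.}
#'   \item{`"dose"`}{absorbed dose in Gy(RBE), non-negative.}
#'   \item{`"mask"`}{binary 0/1 structure mask.}
#'   \item{`"scalar"`}{anything else (e.g. relative stopping power).}
#' }
#'
#' @param values 3D numeric array, `dim(values) == grid$size`.
#' @param grid a [grid3d()].
#' @param kind one of `"ct"`, `"dose"`, `"mask"`, `"scalar"`.
#' @return a `volume3d` object.
#' @export
volume3d <- function(values, grid, kind = c("scalar", "ct", "dose", "mask")) {
  kind <- match.arg(kind)
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (!all(dim(values) == grid$size)) {
    stop("value array dimensions do not match the grid size")
  }
  if (kind == "ct") {
    if (any(values < -1024 | values > 3071)) {
      stop("CT values must lie within [-1024, 3071] HU")
    }
  } else if (kind == "mask") {
    if (!all(values %in% c(0, 1))) stop("mask volumes must be binary 0/1")
  } else if (kind == "dose") {
    if (any(!is.finite(values)) || any(values < 0)) {
      stop("dose values must be finite and non-negative")
    }
  }
  structure(list(values = values, grid = grid, kind = kind),
            class = "volume3d")
}

#' @rdname volume3d
#' @param hu 3D array of Hounsfield units.
#' @export
ct_volume <- function(hu, grid) volume3d(hu, grid, kind = "ct")

#' @rdname volume3d
#' @param gy 3D array of doses in Gy(RBE).
#' @export
dose_volume <- function(gy, grid) volume3d(gy, grid, kind = "dose")

#' @rdname volume3d
#' @param m 3D 0/1 array.
#' @export
mask_volume <- function(m, grid) volume3d(m, grid, kind = "mask")

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("volume3d [%s]: %s voxels, range [%g, %g]\n", x$kind,
              paste(x$grid$size, collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Round HU half-away-from-zero and clamp to the valid CT range
#'
#' CT numbers are integral; synthesis steps therefore re-integerize with
#' half-away-from-zero rounding (so e.g. 0.5 -> 1, -0.5 -> -1) and clamp to
#' \eqn{[-1024, 3071]} HU.
#' @param x numeric vector or array of HU values.
#' @return same shape, integral values within the CT range.
#' @export
round_hu <- function(x) {
  r <- sign(x) * floor(abs(x) + 0.5)
  pmin(pmax(r, -1024), 3071)
}

#' Structure set: named binary masks on a shared grid
#'
#' @param grid a [grid3d()].
#' @param masks named list of `volume3d` masks (or raw 0/1 arrays), all
#'   aligned to `grid`.
#' @param roles named character vector tagging each structure as
#'   `"target-HR"`, `"target-LR"` or `"oar"`.
#' @return a `structure_set` object.
#' @export
structure_set <- function(grid, masks, roles = NULL) {
  if (is.null(names(masks)) || any(names(masks) == "")) {
    stop("all structures must be named")
  }
  masks <- lapply(masks, function(m) {
    if (inherits(m, "volume3d")) {
      stop_if_misaligned(m$grid, grid, "structure masks")
      m
    } else {
      mask_volume(m, grid)
    }
  })
  if (is.null(roles)) {
    roles <- stats::setNames(rep("oar", length(masks)), names(masks))
  }
  structure(list(grid = grid, masks = masks, roles = roles),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("structure_set with", length(x$masks), "structures:\n")
  for (nm in names(x$masks)) {
    cat(sprintf("  %-12s %-10s %d voxels (%.1f cc)\n", nm,
                x$roles[[nm]], sum(x$masks[[nm]]$values),
                sum(x$masks[[nm]]$values) * voxel_volume_cc(x$grid)))
  }
  invisible(x)
}

#' Names of structures with a given role
#' @param ss a [structure_set()].
#' @param role role tag to select (`"target-HR"`, `"target-LR"`, `"oar"`).
#' @return character vector of structure names.
#' @export
structures_with_role <- function(ss, role) {
  names(ss$roles)[ss$roles == role]
}

#' Dense displacement field on a grid
#'
#' Displacements are stored as a 4D array `size[1] x size[2] x size[3] x 3`
#' of mm offsets; the identity field is all zeros. Fields must be finite
#' everywhere.
#'
#' @param displacement 4D numeric array (last dim = 3) of mm displacements.
#' @param grid a [grid3d()].
#' @return a `deformation_field` with a `max_displacement_mm` attribute.
#' @export
deformation_field <- function(displacement, grid) {
  displacement <- as.array(displacement)
  d <- dim(displacement)
  if (length(d) != 4L || d[4] != 3L || !all(d[1:3] == grid$size)) {
    stop("displacement must be a size[1] x size[2] x size[3] x 3 array")
  }
  if (any(!is.finite(displacement))) stop("displacement must be finite")
  mag2 <- displacement[, , , 1]^2 + displacement[, , , 2]^2 +
    displacement[, , , 3]^2
  structure(list(displacement = displacement, grid = grid,
                 max_displacement_mm = sqrt(max(mag2))),
            class = "deformation_field")
}

#' The identity deformation field on a grid
#' @param grid a [grid3d()].
#' @return a [deformation_field()] of all-zero displacement.
#' @export
identity_deformation <- function(grid) {
  deformation_field(array(0, c(grid$size, 3L)), grid)
}
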