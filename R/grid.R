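#' Define a regular 3D sampling grid
#'
#' A `volume_grid` describes the geometry of a 3D image: the number of voxels
#' per axis, the voxel size in mm, and the world-space position (mm) of voxel
#' `(1,1,1)`. All maps, masks and resampling operations in the package are
#' expressed on such grids.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 8).
#' @param voxel_size numeric vector of length 3, mm per axis (each > 0).
#'   A scalar is recycled.
#' @param origin_offset numeric vector of length 3, world coordinates (mm) of
#'   the first voxel. A scalar is recycled.
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(32, 32, 32), voxel_size = 2)
#' g
#' @export
volume_grid <- function(shape, voxel_size = 2, origin_offset = 0) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)))
    stop("'shape' must be 3 finite integers")
  if (any(shape < 8L))
    stop("all grid dimensions must be >= 8 voxels")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("all voxel sizes must be positive")
  origin_offset <- rep_len(as.numeric(origin_offset), 3L)
  structure(list(shape = shape, voxel_size = voxel_size,
                 origin_offset = origin_offset),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels @ %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size, trim = TRUE), collapse = "x"),
              paste(format(x$origin_offset, trim = TRUE), collapse = ", ")))
  invisible(x)
}

# world coordinates (mm) of voxel centres along one axis
grid_axis_coords <- function(grid, axis) {
  grid$origin_offset[axis] + (seq_len(grid$shape[axis]) - 1) * grid$voxel_size[axis]
}

grids_equal <- function(a, b, tol = 1e-8) {
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin_offset - b$origin_offset) < tol)
}

#' Affine matrix (voxel index to world mm) of a grid
#'
#' Returns the 4x4 affine mapping 0-based voxel indices to world coordinates,
#' as stored in NIfTI headers.
#'
#' @param grid a [volume_grid()].
#' @return A 4x4 numeric matrix.
#' @export
affine_matrix <- function(grid) {
  m <- diag(4)
  m[1:3, 1:3] <- diag(grid$voxel_size, 3)
  m[1:3, 4] <- grid$origin_offset
  m
}
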