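# Brain-like masks and mask algebra.

#' Super-ellipsoid template "brain" mask
#'
#' Builds a brain-shaped boolean mask by thresholding a super-ellipsoid
#' centred in the grid: voxels with
#' \eqn{|x/a|^p + |y/b|^p + |z/c|^p \le 1} are inside. With the default
#' exponent 3 the shape is rounder than a box and flatter than a sphere,
#' roughly like a brain's bounding volume.
#'
#' @param grid a [volume_grid()].
#' @param semi_axes_frac semi-axis lengths as fractions of each grid extent.
#' @param exponent super-ellipsoid exponent p.
#' @return A 3D logical array on `grid`.
#' @export
template_brain_mask <- function(grid, semi_axes_frac = c(0.42, 0.42, 0.40),
                                exponent = 3) {
  d <- grid$shape
  semi <- semi_axes_frac * d
  ctr <- (d + 1) / 2
  x <- abs((seq_len(d[1]) - ctr[1]) / semi[1])^exponent
  y <- abs((seq_len(d[2]) - ctr[2]) / semi[2])^exponent
  z <- abs((seq_len(d[3]) - ctr[3]) / semi[3])^exponent
  r <- outer(outer(x, y, `+`), z, `+`)
  r <= 1
}

#' Binary erosion of a 3D mask
#'
#' Erodes with the 6-connected structuring element: a voxel survives only if
#' itself and all six face neighbours are inside the mask. Voxels outside the
#' array are treated as background, so the mask also shrinks at the grid edge.
#'
#' @param mask 3D logical array.
#' @param iterations number of erosion passes (0 returns the input).
#' @return A 3D logical array.
#' @export
binary_erode <- function(mask, iterations = 1L) {
  stopifnot(length(dim(mask)) == 3L)
  iterations <- as.integer(iterations)
  d <- dim(mask)
  for (it in seq_len(iterations)) {
    out <- mask
    for (a in 1:3) {
      # shift +1 / -1 along axis a, padding with FALSE
      perm <- c(a, setdiff(1:3, a))
      m <- aperm(mask, perm)
      up <- m; up[-1, , ] <- m[-d[a], , ]; up[1, , ] <- FALSE
      dn <- m; dn[-d[a], , ] <- m[-1, , ]; dn[d[a], , ] <- FALSE
      keep <- m & up & dn
      out <- out & aperm(keep, order(perm))
    }
    mask <- out
  }
  mask
}

#' Intersect brain masks defined on one grid
#'
#' Voxelwise logical AND of all masks. An empty result is an error; the
#' message names the first mask whose addition emptied the running
#' intersection.
#'
#' @param masks a list of 3D logical arrays with identical dimensions.
#' @return A 3D logical array.
#' @export
intersect_masks <- function(masks) {
  if (length(masks) == 0L) stop("no masks supplied")
  d <- dim(masks[[1]])
  nm <- names(masks)
  if (is.null(nm)) nm <- as.character(seq_along(masks))
  acc <- masks[[1]]
  if (!any(acc)) stop("empty mask intersection: mask '", nm[1], "' is empty")
  for (i in seq_along(masks)[-1]) {
    if (!identical(dim(masks[[i]]), d)) stop("masks are not on the same grid")
    acc <- acc & masks[[i]]
    if (!any(acc))
      stop("empty mask intersection: mask '", nm[i],
           "' excludes all remaining voxels")
  }
  acc
}
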