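# Separable Gaussian smoothing on regular grids.
#
# Convolution is circulant (periodic) along each axis, so smoothed white
# noise is exactly stationary and the smoothness of generated fields is
# analytically known -- Gaussian kernels compose in quadrature:
# FWHM_total^2 = FWHM_a^2 + FWHM_b^2.

#' Convert between FWHM and Gaussian sigma
#'
#' @param fwhm full width at half maximum (any length unit).
#' @return The standard deviation of the Gaussian kernel with that FWHM.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' @rdname fwhm_to_sigma
#' @param sigma Gaussian standard deviation.
#' @export
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

# normalized 1D Gaussian kernel sampled at integer offsets; sums to 1
gaussian_kernel_1d <- function(fwhm_vox) {
  if (fwhm_vox <= 0) return(1)
  sigma <- fwhm_to_sigma(fwhm_vox)
  h <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k / sum(k)
}

# n x n circulant convolution matrix for a symmetric kernel
circulant_matrix <- function(n, kernel) {
  if (length(kernel) == 1L) return(diag(n))
  h <- (length(kernel) - 1L) / 2L
  S <- matrix(0, n, n)
  i <- seq_len(n)
  for (off in seq(-h, h)) {
    j <- ((i - 1L + off) %% n) + 1L
    idx <- cbind(i, j)
    S[idx] <- S[idx] + kernel[off + h + 1L]
  }
  S
}

# Smooth many volumes at once. M is a prod(shape) x n matrix whose columns
# are volumes in column-major voxel order; fwhm_vox is per-axis FWHM in
# voxel units. Returns a matrix of the same shape. Volumes are processed
# one at a time (axis 1 as a left multiply, axis 3 as a right multiply by
# the symmetric circulant, axis 2 via one transpose round-trip), which
# keeps the working set to a single volume.
smooth_matrix <- function(M, shape, fwhm_vox) {
  fwhm_vox <- rep_len(fwhm_vox, 3L)
  if (all(fwhm_vox <= 0)) return(M)
  d <- as.integer(shape)
  S <- lapply(1:3, function(a)
    if (fwhm_vox[a] > 0)
      circulant_matrix(d[a], gaussian_kernel_1d(fwhm_vox[a])) else NULL)
  out <- M
  for (v in seq_len(ncol(M))) {
    A <- array(M[, v], d)
    if (!is.null(S[[1]]))
      A <- array(S[[1]] %*% matrix(A, d[1]), d)
    if (!is.null(S[[3]]))
      A <- array(matrix(A, d[1] * d[2], d[3]) %*% S[[3]], d)
    if (!is.null(S[[2]])) {
      A <- aperm(A, c(2L, 1L, 3L))
      A <- array(S[[2]] %*% matrix(A, d[2]), c(d[2], d[1], d[3]))
      A <- aperm(A, c(2L, 1L, 3L))
    }
    out[, v] <- A
  }
  out
}

#' Smooth a 3D volume with a separable Gaussian kernel
#'
#' Applies periodic (circulant) Gaussian convolution along each axis. The
#' kernel sums to one, so constant fields are preserved.
#'
#' @param vol a 3D numeric array.
#' @param fwhm_vox per-axis FWHM of the kernel in voxel units (scalar or
#'   length 3); 0 disables smoothing along an axis.
#' @return A 3D array of the same dimensions.
#' @export
smooth_volume <- function(vol, fwhm_vox) {
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  array(smooth_matrix(matrix(as.numeric(vol), ncol = 1L), d, fwhm_vox), d)
}

# variance attenuation factor of circulant smoothing applied to unit-variance
# white noise: Var(out) = prod over axes of sum(kernel^2) (exact under
# periodic convolution when the wrapped kernel has negligible self-overlap)
smoothing_var_factor <- function(shape, fwhm_vox) {
  fwhm_vox <- rep_len(fwhm_vox, 3L)
  f <- 1
  for (a in 1:3) {
    k <- circulant_matrix(shape[a], gaussian_kernel_1d(fwhm_vox[a]))[1, ]
    f <- f * sum(k^2)
  }
  f
}

# unit-variance stationary Gaussian field with given smoothness, consuming
# the current RNG stream
smooth_unit_noise <- function(shape, fwhm_vox, n = 1L) {
  M <- matrix(stats::rnorm(prod(shape) * n), ncol = n)
  M <- smooth_matrix(M, shape, fwhm_vox)
  M / sqrt(smoothing_var_factor(shape, fwhm_vox))
}
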