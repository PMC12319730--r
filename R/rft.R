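# Random field theory voxel-wise FWE correction for T fields:
# residual-based smoothness estimation, lattice resel counts, expected Euler
# characteristic of excursion sets, and threshold solving.

#' Estimate field smoothness from standardized residuals
#'
#' Per axis, the variance `v` of first differences of unit-variance
#' standardized residuals (over in-mask neighbour pairs and residual maps)
#' gives `FWHM = sqrt(4 log 2 / v)` in voxel units -- the standard
#' residual-based estimator for a Gaussian autocorrelation field. Each
#' residual map is first centred on its in-mask spatial mean and the rows
#' are then re-standardized, so spatially constant per-subject components
#' (global offsets, subject random effects) do not inflate the apparent
#' smoothness of the noise. Resel counts over the mask lattice follow; see
#' [resel_counts()].
#'
#' @param residuals matrix of standardized residuals, one row per in-mask
#'   voxel (aligned with `which(mask)`), one column per residual map (>= 3),
#'   or a `tstat_result`.
#' @param mask 3D logical analysis mask.
#' @param voxel_size optional mm per axis to also report FWHM in mm.
#' @return An object of class `smoothness_estimate`: `fwhm_vox`, `fwhm_mm`
#'   (or `NULL`), and `resels` = `c(R0, R1, R2, R3)`.
#' @export
estimate_smoothness <- function(residuals, mask, voxel_size = NULL) {
  if (inherits(residuals, "tstat_result")) {
    if (missing(mask)) mask <- residuals$mask
    residuals <- residuals$residuals
  }
  stopifnot(is.matrix(residuals), ncol(residuals) >= 3L,
            nrow(residuals) == sum(mask))
  ok <- rowSums(!is.finite(residuals)) == 0L
  # remove each map's global (in-mask) mean, then restandardize voxels
  residuals <- sweep(residuals, 2L, colMeans(residuals[ok, , drop = FALSE]))
  rsd <- sqrt(rowSums((residuals - rowMeans(residuals))^2) /
                (ncol(residuals) - 1))
  ok <- ok & rsd > 0
  residuals <- residuals / rsd
  pairs <- mask_neighbour_pairs(mask)
  v <- numeric(3)
  for (a in 1:3) {
    pr <- pairs[[a]]
    use <- ok[pr[, 1]] & ok[pr[, 2]]
    if (!any(use)) stop("no usable neighbour pairs along axis ", a)
    D <- residuals[pr[use, 2], , drop = FALSE] -
         residuals[pr[use, 1], , drop = FALSE]
    v[a] <- mean(D^2)
  }
  fwhm <- sqrt(4 * log(2) / v)
  if (any(fwhm < 1))
    warning("estimated FWHM below 1 voxel; RFT approximation degraded")
  structure(list(fwhm_vox = fwhm,
                 fwhm_mm = if (is.null(voxel_size)) NULL else
                   fwhm * rep_len(voxel_size, 3L),
                 resels = resel_counts(mask, fwhm),
                 diff_var = v),
            class = "smoothness_estimate")
}

#' Declare known smoothness (bypassing estimation)
#'
#' Used when the generating kernel is known, to isolate threshold-solver
#' behaviour from estimator error.
#'
#' @param mask 3D logical analysis mask.
#' @param fwhm_vox per-axis FWHM in voxel units (scalar recycled).
#' @return A `smoothness_estimate`.
#' @export
known_smoothness <- function(mask, fwhm_vox) {
  fwhm <- rep_len(as.numeric(fwhm_vox), 3L)
  stopifnot(all(fwhm > 0))
  structure(list(fwhm_vox = fwhm, fwhm_mm = NULL,
                 resels = resel_counts(mask, fwhm), diff_var = NULL),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("<smoothness_estimate> FWHM %s voxels; resels R0=%.2f R1=%.2f R2=%.2f R3=%.2f\n",
              paste(format(round(x$fwhm_vox, 2), trim = TRUE), collapse = "/"),
              x$resels[1], x$resels[2], x$resels[3], x$resels[4]))
  invisible(x)
}

# index pairs (rows of the in-mask matrix) of face neighbours along each axis
mask_neighbour_pairs <- function(mask) {
  d <- dim(mask)
  idx <- array(0L, d)
  idx[mask] <- seq_len(sum(mask))
  out <- vector("list", 3L)
  for (a in 1:3) {
    perm <- c(a, setdiff(1:3, a))
    m <- aperm(idx, perm)
    i1 <- m[-d[a], , , drop = FALSE]
    i2 <- m[-1, , , drop = FALSE]
    both <- i1 > 0L & i2 > 0L
    out[[a]] <- cbind(i1[both], i2[both])
  }
  out
}

#' Resel counts of a mask lattice at given smoothness
#'
#' Counts points, edges, faces and cubes of the in-mask lattice and converts
#' them to 0- to 3-dimensional resolution-element counts with per-axis resel
#' density `1/FWHM`. `R3` is the mask voxel count times the product of the
#' densities (so a cubic mask of side `s` at isotropic FWHM `f` has
#' `R3 = (s/f)^3`); `R1` and `R2` use edge/face counts with the boundary
#' corrections that make them exact for box-shaped masks; `R0` is the Euler
#' characteristic of the lattice.
#'
#' @param mask 3D logical array.
#' @param fwhm_vox per-axis FWHM in voxel units (scalar recycled).
#' @return Numeric vector `c(R0, R1, R2, R3)`.
#' @export
resel_counts <- function(mask, fwhm_vox) {
  fwhm <- rep_len(as.numeric(fwhm_vox), 3L)
  stopifnot(all(fwhm > 0), length(dim(mask)) == 3L)
  d <- dim(mask)
  P <- sum(mask)
  if (P == 0L) stop("mask is empty")
  sh <- function(m, a) { # AND of m with itself shifted by one along axis a
    perm <- c(a, setdiff(1:3, a))
    mm <- aperm(m, perm)
    aperm(mm[-dim(mm)[1], , , drop = FALSE] & mm[-1, , , drop = FALSE],
          order(perm))
  }
  ex <- sh(mask, 1); ey <- sh(mask, 2); ez <- sh(mask, 3)
  Ex <- sum(ex); Ey <- sum(ey); Ez <- sum(ez)
  fxy <- sh(ex, 2); fxz <- sh(ex, 3); fyz <- sh(ey, 3)
  Fxy <- sum(fxy); Fxz <- sum(fxz); Fyz <- sum(fyz)
  C <- sum(sh(fxy, 3))
  r <- 1 / fwhm
  R0 <- P - (Ex + Ey + Ez) + (Fxy + Fxz + Fyz) - C
  R1 <- (Ex - Fxy - Fxz + C) * r[1] + (Ey - Fxy - Fyz + C) * r[2] +
        (Ez - Fxz - Fyz + C) * r[3]
  R2 <- (Fxy - C) * r[1] * r[2] + (Fxz - C) * r[1] * r[3] +
        (Fyz - C) * r[2] * r[3]
  R3 <- P * r[1] * r[2] * r[3]
  c(R0 = R0, R1 = R1, R2 = R2, R3 = R3)
}

# Euler characteristic densities of a Student field (unified RFT result),
# d = 0..3. t may be a vector.
ec_density_t <- function(t, d, df) {
  a <- 4 * log(2)
  cc <- (1 + t^2 / df)^(-(df - 1) / 2)
  switch(as.character(d),
    "0" = stats::pt(t, df, lower.tail = FALSE),
    "1" = sqrt(a) / (2 * pi) * cc,
    "2" = a / (2 * pi)^1.5 * cc * t *
          exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df / 2),
    "3" = a^1.5 / (2 * pi)^2 * cc * ((df - 1) / df * t^2 - 1),
    stop("d must be 0..3"))
}

#' Expected Euler characteristic of a T-field excursion set
#'
#' `sum_d R_d * rho_d(t, df)` with the standard unified EC densities for
#' Student fields. For high thresholds this approximates the family-wise
#' probability of any suprathreshold voxel.
#'
#' @param t threshold (vectorized).
#' @param df degrees of freedom of the field.
#' @param resels a `smoothness_estimate`, or a numeric vector
#'   `c(R0, R1, R2, R3)`.
#' @return Expected EC (same length as `t`).
#' @export
ec_expected <- function(t, df, resels) {
  R <- unname(if (inherits(resels, "smoothness_estimate")) resels$resels
              else resels)
  stopifnot(length(R) == 4L, df > 0)
  R[1] * ec_density_t(t, 0, df) + R[2] * ec_density_t(t, 1, df) +
    R[3] * ec_density_t(t, 2, df) + R[4] * ec_density_t(t, 3, df)
}

#' Solve the voxel-wise FWE threshold from the expected EC
#'
#' Finds `t` with `ec_expected(t, df, resels) = alpha` by monotone root
#' solving on the decreasing branch (the bracket starts at the uncorrected
#' Student quantile). With resels `c(1, 0, 0, 0)` this reduces to the
#' uncorrected one-tailed Student threshold.
#'
#' @param alpha family-wise error level in (0, 1), default 0.05.
#' @param df degrees of freedom used for thresholding (scalar; under Welch
#'   the median per-voxel df).
#' @param resels a `smoothness_estimate` or `c(R0, R1, R2, R3)`.
#' @return An object of class `fwe_threshold`: `alpha`, `t_threshold`, `df`,
#'   `method = "rft"`.
#' @export
solve_threshold <- function(alpha = 0.05, df, resels) {
  stopifnot(alpha > 0, alpha < 1, df > 0)
  f <- function(t) ec_expected(t, df, resels) - alpha
  lo <- max(0.5, stats::qt(1 - alpha, df))
  hi <- 50
  if (f(lo) < 0) lo <- 0.5 # tiny search volumes: threshold below qt(1-alpha)
  if (f(lo) < 0 || f(hi) > 0)
    stop("no FWE threshold root in [", round(lo, 2), ", 50]")
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  if (abs(ec_expected(root, df, resels) - alpha) > 1e-8)
    stop("threshold solver did not converge to tolerance")
  structure(list(alpha = alpha, t_threshold = root, df = df, method = "rft"),
            class = "fwe_threshold")
}

#' @export
print.fwe_threshold <- function(x, ...) {
  cat(sprintf("<fwe_threshold> t >= %.4f (alpha = %g FWE, df = %s, %s)\n",
              x$t_threshold, x$alpha, format(round(x$df, 2)), x$method))
  invisible(x)
}

#' Count suprathreshold voxels in a t map
#'
#' Detection is the closed comparison `t >= t_threshold` over in-mask voxels
#' with a defined t value.
#'
#' @param tmap a `tstat_result` (or numeric vector of t values).
#' @param threshold a `fwe_threshold` (or a number).
#' @return An object of class `detection_result`:
#'   `n_suprathreshold_voxels`, `any_detection`, `max_t`.
#' @export
detect <- function(tmap, threshold) {
  tv <- if (inherits(tmap, "tstat_result")) tmap$t else as.numeric(tmap)
  u <- if (inherits(threshold, "fwe_threshold")) threshold$t_threshold else
    as.numeric(threshold)
  tv <- tv[is.finite(tv)]
  if (length(tv) == 0L) stop("no defined t values to threshold")
  n_sup <- sum(tv >= u)
  structure(list(n_suprathreshold_voxels = n_sup,
                 any_detection = n_sup >= 1L, max_t = max(tv),
                 t_threshold = u),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d voxels >= %.4f (max t = %.4f)%s\n",
              x$n_suprathreshold_voxels, x$t_threshold, x$max_t,
              if (x$any_detection) " *" else ""))
  invisible(x)
}
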