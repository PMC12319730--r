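# Voxel-wise one-tailed two-sample t statistics between groups of
# harmonized contrast maps.

#' Randomly assign subjects to two disjoint groups
#'
#' Draws `2 * n_per_group` distinct subjects uniformly without replacement
#' from the pool; the first half forms group 1.
#'
#' @param pool vector of subject ids.
#' @param n_per_group group size (default 50).
#' @param pipeline1,pipeline2 pipeline labels attached to each group.
#' @param seed optional integer; if given, the draw uses its own seeded
#'   stream (caller's RNG untouched), otherwise the current stream.
#' @return An object of class `group_assignment` with `group1_ids`,
#'   `group2_ids`, `pipeline1`, `pipeline2`.
#' @export
sample_groups <- function(pool, n_per_group = 50L,
                          pipeline1 = "", pipeline2 = "", seed = NULL) {
  n_per_group <- as.integer(n_per_group)
  if (length(pool) < 2L * n_per_group)
    stop("pool of ", length(pool), " subjects is too small for two groups of ",
         n_per_group)
  draw <- function() sample(pool, 2L * n_per_group, replace = FALSE)
  ids <- if (is.null(seed)) draw() else
    with_preserved_seed({ set.seed(as.integer(seed)); draw() })
  structure(list(group1_ids = ids[seq_len(n_per_group)],
                 group2_ids = ids[n_per_group + seq_len(n_per_group)],
                 pipeline1 = pipeline1, pipeline2 = pipeline2),
            class = "group_assignment")
}

# stack a list of contrast_maps into an in-mask matrix (voxels x subjects)
stack_maps <- function(maps, mask) {
  keep <- which(mask)
  do.call(cbind, lapply(maps, function(m) {
    stopifnot(inherits(m, "contrast_map"))
    as.numeric(m$values)[keep]
  }))
}

#' Voxel-wise one-tailed two-sample t map
#'
#' Computes, per in-mask voxel, `t = (m1 - m2) / se` with the standard error
#' from either the Welch unequal-variance formula (per-voxel Satterthwaite
#' df) or the pooled-variance formula (scalar df `n1 + n2 - 2`). Direction
#' `"group2_gt_group1"` negates the map. Per-subject standardized residual
#' volumes (`(x - group mean) / group sd`) are retained for smoothness
#' estimation. Voxels where both groups have zero variance get an undefined
#' t; they are flagged, counted, and excluded from detection.
#'
#' @param group1,group2 either numeric matrices (in-mask voxels x subjects,
#'   rows aligned with `which(mask)`) or lists of [contrast_map()]s on one
#'   grid.
#' @param mask 3D logical array giving the analysis mask.
#' @param variance_mode `"welch"` (default) or `"pooled"`.
#' @param direction `"group1_gt_group2"` (default) or `"group2_gt_group1"`.
#' @return An object of class `tstat_result`: `t` (vector over in-mask
#'   voxels), `df` (per-voxel for Welch, scalar for pooled), `df_scalar`
#'   (median Welch df, or the pooled df) used for thresholding, `residuals`
#'   (voxels x (n1+n2)), `undefined` flags, `n1`, `n2`, `mask`, `direction`,
#'   `variance_mode`.
#' @export
two_sample_tmap <- function(group1, group2, mask,
                            variance_mode = c("welch", "pooled"),
                            direction = c("group1_gt_group2",
                                          "group2_gt_group1")) {
  variance_mode <- match.arg(variance_mode)
  direction <- match.arg(direction)
  if (is.list(group1)) group1 <- stack_maps(group1, mask)
  if (is.list(group2)) group2 <- stack_maps(group2, mask)
  n1 <- ncol(group1); n2 <- ncol(group2)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 maps per group")
  if (nrow(group1) != nrow(group2) || nrow(group1) != sum(mask))
    stop("group matrices must have one row per in-mask voxel")

  m1 <- rowMeans(group1); m2 <- rowMeans(group2)
  v1 <- rowSums((group1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((group2 - m2)^2) / (n2 - 1)

  if (variance_mode == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  undefined <- se2 <= 0 | !is.finite(se2)
  tval <- (m1 - m2) / sqrt(se2)
  tval[undefined] <- NA_real_
  if (direction == "group2_gt_group1") tval <- -tval

  sd1 <- sqrt(v1); sd2 <- sqrt(v2)
  sd1[sd1 <= 0] <- NA_real_; sd2[sd2 <= 0] <- NA_real_
  residuals <- cbind((group1 - m1) / sd1, (group2 - m2) / sd2)

  df_scalar <- if (variance_mode == "pooled") n1 + n2 - 2 else
    stats::median(df[!undefined])

  structure(list(t = tval, df = df, df_scalar = df_scalar,
                 direction = direction, variance_mode = variance_mode,
                 residuals = residuals, undefined = undefined,
                 n_undefined = sum(undefined), n1 = n1, n2 = n2, mask = mask),
            class = "tstat_result")
}

#' @export
print.tstat_result <- function(x, ...) {
  cat(sprintf(
    "<tstat_result> %s, %s df %s, n1=%d n2=%d, %d voxels (%d undefined), max t = %.3f\n",
    x$direction, x$variance_mode, format(round(x$df_scalar, 2)),
    x$n1, x$n2, length(x$t), x$n_undefined, max(x$t, na.rm = TRUE)))
  invisible(x)
}

#' Unpack a t map vector into a 3D array
#'
#' @param tstat a `tstat_result`.
#' @param fill value for voxels outside the mask.
#' @return A 3D array on the analysis grid.
#' @export
tstat_as_array <- function(tstat, fill = NA_real_) {
  out <- array(fill, dim(tstat$mask))
  out[tstat$mask] <- tstat$t
  out
}
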