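# Harmonization: one grid, one mask, one unit scale.
#
# Order of operations: resample (third-order spline) -> intersect masks
# (across all pipelines) -> apply common mask -> rescale to percent BOLD.

# Natural-cubic-spline resampling is linear in the data, so interpolation
# along one axis is a dense operator built once by pushing basis vectors
# through stats::splinefun. Returns the operator and the in-FOV indicator
# for the target coordinates (no extrapolation: outside targets drop out).
spline_axis_operator <- function(src_coords, dst_coords) {
  n <- length(src_coords)
  inside <- dst_coords >= min(src_coords) & dst_coords <= max(src_coords)
  W <- matrix(0, length(dst_coords), n)
  basis <- diag(n)
  for (j in seq_len(n)) {
    f <- stats::splinefun(src_coords, basis[, j], method = "natural")
    W[, j] <- f(dst_coords)
  }
  W[!inside, ] <- 0
  list(W = W, inside = inside)
}

nn_axis_index <- function(src_coords, dst_coords) {
  idx <- vapply(dst_coords, function(x) which.min(abs(src_coords - x)),
                integer(1))
  inside <- dst_coords >= min(src_coords) & dst_coords <= max(src_coords)
  list(idx = idx, inside = inside)
}

# resample many volumes (columns of M) from src_grid to dst_grid
resample_matrix <- function(M, src_grid, dst_grid) {
  ops <- lapply(1:3, function(a)
    spline_axis_operator(grid_axis_coords(src_grid, a),
                         grid_axis_coords(dst_grid, a)))
  if (!any(ops[[1]]$inside) || !any(ops[[2]]$inside) || !any(ops[[3]]$inside))
    stop("no overlap between source and template fields of view")
  ds <- src_grid$shape; dd <- dst_grid$shape
  n <- ncol(M)
  A <- array(M, c(ds, n))
  A <- array(ops[[1]]$W %*% matrix(A, nrow = ds[1]), c(dd[1], ds[2], ds[3], n))
  Ap <- aperm(A, c(2L, 1L, 3L, 4L))
  Ap <- array(ops[[2]]$W %*% matrix(Ap, nrow = ds[2]), c(dd[2], dd[1], ds[3], n))
  A <- aperm(Ap, c(2L, 1L, 3L, 4L))
  Ap <- aperm(A, c(3L, 2L, 1L, 4L))
  Ap <- array(ops[[3]]$W %*% matrix(Ap, nrow = ds[3]), c(dd[3], dd[2], dd[1], n))
  A <- aperm(Ap, c(3L, 2L, 1L, 4L))
  inside <- outer(outer(ops[[1]]$inside, ops[[2]]$inside, `&`),
                  ops[[3]]$inside, `&`)
  list(values = matrix(A, nrow = prod(dd)), inside = inside)
}

# nearest-neighbour mask resampling, restricted to in-FOV voxels
resample_mask <- function(mask, src_grid, dst_grid) {
  ops <- lapply(1:3, function(a)
    nn_axis_index(grid_axis_coords(src_grid, a),
                  grid_axis_coords(dst_grid, a)))
  out <- mask[ops[[1]]$idx, ops[[2]]$idx, ops[[3]]$idx, drop = FALSE]
  inside <- outer(outer(ops[[1]]$inside, ops[[2]]$inside, `&`),
                  ops[[3]]$inside, `&`)
  out & inside
}

#' Resample a contrast map onto a template grid
#'
#' Values are interpolated with a third-order (natural cubic) spline,
#' separably along each axis; the mask is resampled nearest-neighbour and
#' restricted to voxels strictly inside the source field of view, so no
#' spline extrapolation ever enters downstream statistics.
#'
#' @param map a [contrast_map()].
#' @param template target [volume_grid()].
#' @return A `contrast_map` on `template`.
#' @export
resample_to_template <- function(map, template) {
  stopifnot(inherits(map, "contrast_map"), inherits(template, "volume_grid"))
  if (grids_equal(map$grid, template)) return(map)
  rs <- resample_matrix(matrix(as.numeric(map$values), ncol = 1L),
                        map$grid, template)
  mask <- resample_mask(map$mask, map$grid, template)
  if (!any(mask)) stop("resampled mask is empty on the template grid")
  vals <- array(rs$values, template$shape)
  vals[!rs$inside] <- 0
  contrast_map(vals, grid = template, mask = mask, units = map$units,
               subject_id = map$subject_id, pipeline_label = map$pipeline_label)
}

#' Rescale a raw contrast map to percent BOLD
#'
#' Multiplies values by the rule's factor and marks the map as percent BOLD.
#' Applying it to an already-rescaled map is an error (double-scaling guard).
#'
#' @param map a [contrast_map()] in raw pipeline units.
#' @param rule a [rescale_rule()].
#' @return A `contrast_map` in percent BOLD units.
#' @export
rescale <- function(map, rule) {
  stopifnot(inherits(map, "contrast_map"), inherits(rule, "rescale_rule"))
  if (map$units != "raw_pipeline_units")
    stop("map is already in percent BOLD units (double-scaling guard)")
  map$values <- map$values * rule$factor
  map$units <- "percent_BOLD"
  map
}

#' Harmonize a whole cohort onto one grid, mask and unit scale
#'
#' Resamples every pipeline's maps and mask to the template grid, intersects
#' all pipeline masks into a common mask, zeroes values outside it, and
#' rescales raw units to percent BOLD using the per-software-style rules.
#' Already-harmonized cohorts pass through unchanged (idempotence), with the
#' rescaling step skipped.
#'
#' @param cohort an `fmri_cohort` from [generate_cohort()] (or a previous
#'   harmonization).
#' @param template target [volume_grid()]; default is the acquisition grid.
#' @param rules named list of [rescale_rule()] keyed by software style; every
#'   pipeline's style must have a rule.
#' @return A harmonized `fmri_cohort` with `common_mask` set and a `log` of
#'   the steps applied.
#' @export
harmonize_cohort <- function(cohort, template = NULL,
                             rules = default_rescale_rules()) {
  stopifnot(inherits(cohort, "fmri_cohort"))
  if (is.null(template)) template <- cohort$grid
  log <- cohort$log
  for (lab in names(cohort$pipelines)) {
    style <- cohort$pipelines[[lab]]$software_style
    if (cohort$units[[lab]] == "raw_pipeline_units" && is.null(rules[[style]]))
      stop("no rescale rule for pipeline '", lab, "' (style ", style, ")")
  }
  for (lab in names(cohort$data)) {
    if (!grids_equal(cohort$grids[[lab]], template)) {
      rs <- resample_matrix(cohort$data[[lab]], cohort$grids[[lab]], template)
      vals <- rs$values
      vals[!as.vector(rs$inside), ] <- 0
      cohort$data[[lab]] <- vals
      cohort$masks[[lab]] <- resample_mask(cohort$masks[[lab]],
                                           cohort$grids[[lab]], template)
      cohort$grids[[lab]] <- template
      log <- c(log, sprintf("resampled pipeline '%s' to template grid", lab))
    }
  }
  common <- intersect_masks(cohort$masks)
  keep <- as.vector(common)
  for (lab in names(cohort$data)) {
    cohort$data[[lab]][!keep, ] <- 0
    log <- c(log, sprintf("applied common mask to pipeline '%s'", lab))
    if (cohort$units[[lab]] == "raw_pipeline_units") {
      style <- cohort$pipelines[[lab]]$software_style
      f <- rules[[style]]$factor
      cohort$data[[lab]] <- cohort$data[[lab]] * f
      cohort$units[[lab]] <- "percent_BOLD"
      log <- c(log, sprintf("rescaled pipeline '%s' by %g", lab, f))
    } else {
      log <- c(log, sprintf("pipeline '%s' already in percent BOLD; rescale skipped", lab))
    }
  }
  cohort$grid <- template
  cohort$common_mask <- common
  cohort$harmonized <- TRUE
  cohort$log <- log
  cohort
}
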