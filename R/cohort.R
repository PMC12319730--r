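# Synthetic multi-pipeline cohort generator.
#
# Generative model for subject i on the acquisition grid:
#   L_i = mu + b_i + eps_i
# with mu the (blob) effect field in percent BOLD, b_i ~ N(0, subject_sd^2)
# a scalar subject random effect, and eps_i stationary Gaussian noise of
# standard deviation noise_sd and smoothness noise_fwhm. The SAME (b_i,
# eps_i) realization underlies every pipeline's map for subject i: pipelines
# transform one acquisition. Pipeline p emits
#   unit_scale_p * [ Smooth(gain_p mu + b_i + sqrt(f_p) eps_i, fwhm_p)
#                    + offset_field_p ]
# resampled to its own grid, with its own eroded brain mask. The gain acts
# on the true effect only (pipelines mis-estimate signal amplitude, not
# noise), so gain = 0 pipelines carry pure noise.

#' Configure a synthetic cohort
#'
#' @param n_subjects number of subjects in the pool (default 1080, the size
#'   of a large young-adult cohort).
#' @param pipelines list of [pipeline_spec()]; labels must be unique.
#' @param true_effect_blobs list of blobs, each a list with `center` (voxel
#'   triple, `NULL` = grid centre), `radius` (mm) and `amplitude` (percent
#'   BOLD). Blobs are hard balls; pipeline smoothing makes them smooth.
#' @param subject_sd percent BOLD; sd of the scalar between-subject effect.
#' @param noise_sd percent BOLD; sd of the within-map noise after smoothing
#'   to `noise_fwhm`.
#' @param noise_fwhm mm; intrinsic spatial smoothness of the noise.
#' @param grid acquisition [volume_grid()].
#' @param seed integer root seed; per-subject substreams are derived from it
#'   (see Details), so cohorts are bit-reproducible.
#' @param subject_effect `"scalar"` (default) or `"field"`; with `"field"`
#'   the subject effect is a smooth unit-variance field times `subject_sd`
#'   instead of a constant.
#'
#' @details Subject i draws from a substream seeded with
#' `(seed + 1000003 * i) mod (2^31 - 1)`; pipeline-level fields (bias
#' fields) use `(seed + 7777 + 131 * j) mod (2^31 - 1)` for pipeline j.
#' This makes generation order-independent and parallel-safe.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 1080L,
                          pipelines = default_pipelines(),
                          true_effect_blobs = list(
                            list(center = NULL, radius = 8, amplitude = 1)),
                          subject_sd = 0.1,
                          noise_sd = 0.8,
                          noise_fwhm = 4,
                          grid = volume_grid(c(32L, 32L, 32L), voxel_size = 2),
                          seed = 1L,
                          subject_effect = c("scalar", "field")) {
  subject_effect <- match.arg(subject_effect)
  stopifnot(n_subjects >= 2, subject_sd >= 0, noise_sd > 0, noise_fwhm >= 0,
            inherits(grid, "volume_grid"), length(pipelines) >= 1L)
  labels <- vapply(pipelines, function(p) p$label, character(1))
  if (anyDuplicated(labels)) stop("pipeline labels must be unique")
  names(pipelines) <- labels
  structure(list(n_subjects = as.integer(n_subjects), pipelines = pipelines,
                 true_effect_blobs = true_effect_blobs,
                 subject_sd = subject_sd, noise_sd = noise_sd,
                 noise_fwhm = noise_fwhm, grid = grid,
                 seed = as.integer(seed), subject_effect = subject_effect),
            class = "cohort_config")
}

subject_seed <- function(seed, i) {
  as.integer((as.double(seed) + 1000003 * i) %% 2147483647)
}

pipeline_seed <- function(seed, j) {
  as.integer((as.double(seed) + 7777 + 131 * j) %% 2147483647)
}

# run code with its own RNG stream, restoring the caller's stream after
with_preserved_seed <- function(code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

# sum of hard-ball blob fields, as a vector over the grid
blob_field <- function(grid, blobs) {
  d <- grid$shape
  mu <- numeric(prod(d))
  if (length(blobs) == 0L) return(mu)
  ax <- lapply(1:3, function(a) seq_len(d[a]))
  for (b in blobs) {
    ctr <- if (is.null(b$center)) (d + 1) / 2 else as.numeric(b$center)
    r_vox <- b$radius / grid$voxel_size
    dx2 <- ((ax[[1]] - ctr[1]) / r_vox[1])^2
    dy2 <- ((ax[[2]] - ctr[2]) / r_vox[2])^2
    dz2 <- ((ax[[3]] - ctr[3]) / r_vox[3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    mu <- mu + b$amplitude * as.numeric(inside)
  }
  mu
}

#' Generate a synthetic multi-pipeline cohort
#'
#' Draws one latent acquisition per subject and pushes it through every
#' pipeline transform. Deterministic given `config$seed`; the caller's RNG
#' state is left untouched.
#'
#' @param config a [cohort_config()].
#' @return An object of class `fmri_cohort`: a list with the acquisition
#'   `grid`, `subject_ids`, the `pipelines` specs, per-pipeline value
#'   matrices (`data`, voxels x subjects, column-major voxel order),
#'   per-pipeline masks and grids, and per-pipeline `units`
#'   (`"raw_pipeline_units"` here; [harmonize_cohort()] converts to percent
#'   BOLD).
#' @seealso [get_contrast_map()], [write_cohort()], [harmonize_cohort()]
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_preserved_seed({
    grid <- config$grid
    d <- grid$shape
    nvox <- prod(d)
    n <- config$n_subjects
    fwhm_noise_vox <- config$noise_fwhm / grid$voxel_size

    mu <- blob_field(grid, config$true_effect_blobs)

    b <- numeric(n)
    E <- matrix(0, nvox, n)
    Bfield <- if (config$subject_effect == "field") matrix(0, nvox, n) else NULL
    for (i in seq_len(n)) {
      set.seed(subject_seed(config$seed, i))
      b[i] <- stats::rnorm(1) * config$subject_sd
      E[, i] <- stats::rnorm(nvox)
      if (!is.null(Bfield))
        Bfield[, i] <- config$subject_sd * smooth_unit_noise(d, fwhm_noise_vox)
    }
    E <- smooth_matrix(E, d, fwhm_noise_vox)
    E <- E * (config$noise_sd / sqrt(smoothing_var_factor(d, fwhm_noise_vox)))

    template_mask <- template_brain_mask(grid)

    data <- list(); masks <- list(); grids <- list(); units <- list()
    for (j in seq_along(config$pipelines)) {
      p <- config$pipelines[[j]]
      L <- E * sqrt(p$noise_variance_factor)
      if (is.null(Bfield)) {
        L <- sweep(L, 2L, b, `+`)
      } else {
        L <- L + Bfield
      }
      L <- L + p$gain * mu
      fwhm_p_vox <- p$smoothing_fwhm / grid$voxel_size
      L <- smooth_matrix(L, d, fwhm_p_vox)
      if (p$offset_field_amplitude > 0) {
        set.seed(pipeline_seed(config$seed, j))
        offset <- p$offset_field_amplitude *
          smooth_unit_noise(d, pmax(fwhm_p_vox, fwhm_noise_vox))
        L <- L + as.numeric(offset)
      }
      L <- p$unit_scale * L
      mask_p <- binary_erode(template_mask, p$mask_erosion)
      grid_p <- if (is.null(p$grid)) grid else p$grid
      if (!grids_equal(grid_p, grid)) {
        rs <- resample_matrix(L, grid, grid_p)
        L <- rs$values
        mask_p <- resample_mask(mask_p, grid, grid_p)
      }
      data[[p$label]] <- L
      masks[[p$label]] <- mask_p
      grids[[p$label]] <- grid_p
      units[[p$label]] <- "raw_pipeline_units"
    }

    structure(list(config = config, grid = grid,
                   subject_ids = seq_len(n), pipelines = config$pipelines,
                   data = data, masks = masks, grids = grids, units = units,
                   harmonized = FALSE, common_mask = NULL, log = character(0)),
              class = "fmri_cohort")
  })
}

#' @export
print.fmri_cohort <- function(x, ...) {
  cat(sprintf("<fmri_cohort> %d subjects x %d pipelines (%s), %s%s\n",
              length(x$subject_ids), length(x$pipelines),
              paste(names(x$pipelines), collapse = ", "),
              paste(x$grid$shape, collapse = "x"),
              if (isTRUE(x$harmonized)) ", harmonized" else ""))
  invisible(x)
}

#' Extract one subject's contrast map from a cohort
#'
#' @param cohort an `fmri_cohort`.
#' @param subject_id integer subject id.
#' @param pipeline pipeline label.
#' @return An object of class `contrast_map`: 3D `values` array, `grid`,
#'   logical `mask`, `units`, `subject_id` and `pipeline_label`.
#' @export
get_contrast_map <- function(cohort, subject_id, pipeline) {
  stopifnot(inherits(cohort, "fmri_cohort"))
  if (!pipeline %in% names(cohort$data)) stop("unknown pipeline: ", pipeline)
  col <- match(subject_id, cohort$subject_ids)
  if (is.na(col)) stop("unknown subject_id: ", subject_id)
  grid_p <- cohort$grids[[pipeline]]
  contrast_map(array(cohort$data[[pipeline]][, col], grid_p$shape),
               grid = grid_p, mask = cohort$masks[[pipeline]],
               units = cohort$units[[pipeline]],
               subject_id = subject_id, pipeline_label = pipeline)
}

#' Construct a contrast map object
#'
#' @param values 3D numeric array on `grid`.
#' @param grid a [volume_grid()].
#' @param mask 3D logical array on the same grid (default: all voxels).
#' @param units `"raw_pipeline_units"` or `"percent_BOLD"`.
#' @param subject_id,pipeline_label identifiers carried through the pipeline.
#' @return An object of class `contrast_map`.
#' @export
contrast_map <- function(values, grid, mask = NULL,
                         units = c("raw_pipeline_units", "percent_BOLD"),
                         subject_id = NA_integer_, pipeline_label = "") {
  units <- match.arg(units)
  stopifnot(inherits(grid, "volume_grid"),
            identical(as.integer(dim(values)), grid$shape))
  if (is.null(mask)) mask <- array(TRUE, grid$shape)
  stopifnot(identical(dim(mask), dim(values)))
  if (!any(mask)) stop("contrast map mask is empty")
  if (any(!is.finite(values[mask])))
    stop("contrast map has non-finite values inside its mask")
  structure(list(values = values, grid = grid, mask = mask, units = units,
                 subject_id = subject_id, pipeline_label = pipeline_label),
            class = "contrast_map")
}

#' @export
print.contrast_map <- function(x, ...) {
  cat(sprintf("<contrast_map> subject %s, pipeline '%s', %s, %d in-mask voxels [%s]\n",
              x$subject_id, x$pipeline_label,
              paste(x$grid$shape, collapse = "x"), sum(x$mask), x$units))
  invisible(x)
}

#' Write a cohort to NIfTI files with a CSV manifest
#'
#' Writes one `.nii.gz` contrast map per (subject, pipeline), one mask per
#' pipeline, and `manifest.csv` with columns `subject_id`, `pipeline_label`,
#' `path`. The NIfTI affine encodes voxel size and origin offset; values are
#' stored as float32.
#'
#' @param cohort an `fmri_cohort`.
#' @param directory output directory (created if missing).
#' @return Invisibly, the manifest `data.frame`.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "fmri_cohort"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  rows <- list()
  for (lab in names(cohort$data)) {
    grid_p <- cohort$grids[[lab]]
    mask_path <- file.path(directory, sprintf("mask_%s.nii.gz", lab))
    write_nifti_volume(cohort$masks[[lab]] * 1, grid_p, mask_path,
                       datatype = "uint8")
    for (k in seq_along(cohort$subject_ids)) {
      sid <- cohort$subject_ids[k]
      path <- file.path(directory, sprintf("sub-%04d_%s.nii.gz", sid, lab))
      write_nifti_volume(array(cohort$data[[lab]][, k], grid_p$shape),
                         grid_p, path, datatype = "float")
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = sid, pipeline_label = lab, path = path,
                   stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# write one volume with the grid geometry in the sform/qform
write_nifti_volume <- function(values, grid, path, datatype = "float") {
  img <- RNifti::asNifti(values)
  img <- RNifti::`pixdim<-`(img, grid$voxel_size)
  aff <- structure(affine_matrix(grid), code = 2L)
  img <- RNifti::`qform<-`(img, aff)
  img <- RNifti::`sform<-`(img, aff)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a contrast map from a NIfTI file
#'
#' Reconstructs the [volume_grid()] from the image header (voxel sizes and
#' the affine's translation column).
#'
#' @param path NIfTI file.
#' @param mask optional companion mask file (or 3D logical array).
#' @param units unit state of the stored values.
#' @param subject_id,pipeline_label identifiers to attach.
#' @return A [contrast_map()].
#' @export
read_contrast_map <- function(path, mask = NULL,
                              units = c("raw_pipeline_units", "percent_BOLD"),
                              subject_id = NA_integer_, pipeline_label = "") {
  units <- match.arg(units)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  grid <- volume_grid(dim(img), voxel_size = RNifti::pixdim(img),
                      origin_offset = aff[1:3, 4])
  if (is.character(mask)) mask <- RNifti::readNifti(mask) > 0
  contrast_map(array(as.numeric(img), dim(img)), grid, mask = mask,
               units = units, subject_id = subject_id,
               pipeline_label = pipeline_label)
}

#' Read a cohort configuration from YAML
#'
#' The file mirrors [cohort_config()] field names; pipelines are a list of
#' mappings mirroring [pipeline_spec()] fields (with optional `grid:` as
#' `shape`/`voxel_size`/`origin_offset`).
#'
#' @param path path to a YAML file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  parse_grid <- function(g) {
    if (is.null(g)) return(NULL)
    volume_grid(g$shape,
                voxel_size = if (is.null(g$voxel_size)) 2 else g$voxel_size,
                origin_offset = if (is.null(g$origin_offset)) 0 else g$origin_offset)
  }
  pipelines <- lapply(y$pipelines, function(p) {
    args <- p
    args$grid <- parse_grid(p$grid)
    do.call(pipeline_spec, args)
  })
  args <- y
  args$pipelines <- pipelines
  args$grid <- if (is.null(y$grid))
    volume_grid(c(32L, 32L, 32L), voxel_size = 2) else parse_grid(y$grid)
  do.call(cohort_config, args)
}
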