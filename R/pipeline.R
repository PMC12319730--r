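# Parameterized subject-level pipelines.
#
# A pipeline here is the transform a given preprocessing + first-level
# modelling chain applies to one subject's latent contrast map: additional
# spatial smoothing, a software-dependent unit scale, a multiplicative gain
# (emulating HRF-model / motion-regressor amplitude differences), a smooth
# additive bias field, a noise-variance factor, its own sampling grid, and
# its own (eroded) brain mask.

#' Describe one subject-level pipeline
#'
#' @param label unique pipeline name.
#' @param software_style `"SPM-like"` or `"FSL-like"`; sets the default raw
#'   unit scale (2.5x percent BOLD for SPM-like, 100x for FSL-like).
#' @param smoothing_fwhm mm; additional Gaussian smoothing this pipeline
#'   applies to the latent map. The total smoothness of its output combines
#'   with the cohort's intrinsic noise FWHM in quadrature.
#' @param unit_scale multiplicative factor from percent BOLD to the
#'   pipeline's raw units; default set by `software_style`.
#' @param gain multiplicative factor on the true effect field (1 = a
#'   faithful pipeline; pipelines mis-estimate signal amplitude, not noise).
#' @param offset_field_amplitude percent BOLD; standard deviation of a smooth
#'   additive pipeline bias field (0 = none).
#' @param noise_variance_factor unitless > 0; scales the variance of the
#'   shared noise realization as seen through this pipeline.
#' @param grid optional [volume_grid()] the pipeline resamples its output to;
#'   `NULL` keeps the cohort acquisition grid.
#' @param mask_erosion non-negative integer; erosion passes applied to the
#'   template brain mask to form this pipeline's own mask.
#' @return An object of class `pipeline_spec`.
#' @examples
#' pipeline_spec("fsl-s5", "FSL-like", smoothing_fwhm = 5)
#' @export
pipeline_spec <- function(label,
                          software_style = c("SPM-like", "FSL-like"),
                          smoothing_fwhm = 5,
                          unit_scale = NULL,
                          gain = 1,
                          offset_field_amplitude = 0,
                          noise_variance_factor = 1,
                          grid = NULL,
                          mask_erosion = 0L) {
  software_style <- match.arg(software_style)
  if (is.null(unit_scale))
    unit_scale <- if (software_style == "SPM-like") 2.5 else 100
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            smoothing_fwhm >= 0, unit_scale > 0,
            noise_variance_factor > 0, mask_erosion >= 0)
  if (!is.null(grid) && !inherits(grid, "volume_grid"))
    stop("'grid' must be a volume_grid or NULL")
  structure(list(label = label, software_style = software_style,
                 smoothing_fwhm = smoothing_fwhm, unit_scale = unit_scale,
                 gain = gain, offset_field_amplitude = offset_field_amplitude,
                 noise_variance_factor = noise_variance_factor,
                 grid = grid, mask_erosion = as.integer(mask_erosion)),
            class = "pipeline_spec")
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat(sprintf(
    "<pipeline_spec> '%s' (%s): smoothing %g mm, unit scale %g, gain %g,\n  offset sd %g, noise variance x%g, mask erosion %d%s\n",
    x$label, x$software_style, x$smoothing_fwhm, x$unit_scale, x$gain,
    x$offset_field_amplitude, x$noise_variance_factor, x$mask_erosion,
    if (is.null(x$grid)) "" else ", own grid"))
  invisible(x)
}

#' Default pair of pipelines (one per software style)
#'
#' Two faithful pipelines with 5 mm smoothing that differ only in software
#' unit scale and in mask erosion (0 vs 1 pass), so harmonization has real
#' work to do while group statistics stay exchangeable.
#'
#' @return A list of two [pipeline_spec()] objects.
#' @export
default_pipelines <- function() {
  list(
    pipeline_spec("spm-s5", "SPM-like", smoothing_fwhm = 5, mask_erosion = 0L),
    pipeline_spec("fsl-s5", "FSL-like", smoothing_fwhm = 5, mask_erosion = 1L)
  )
}

#' Unit-rescaling rule for one software style
#'
#' Raw SPM-like contrast maps are about 2.5x percent BOLD change and FSL-like
#' maps are scaled to 10,000 (100x percent BOLD). The harmonization factors
#' back to percent BOLD are therefore 100/250 = 0.4 and 100/10,000 = 0.01.
#'
#' @param software_style `"SPM-like"` or `"FSL-like"`.
#' @param factor positive multiplicative factor; default 0.4 for SPM-like,
#'   0.01 for FSL-like.
#' @return An object of class `rescale_rule`.
#' @export
rescale_rule <- function(software_style = c("SPM-like", "FSL-like"),
                         factor = NULL) {
  software_style <- match.arg(software_style)
  if (is.null(factor))
    factor <- if (software_style == "SPM-like") 0.4 else 0.01
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  structure(list(software_style = software_style, factor = factor),
            class = "rescale_rule")
}

#' Default rescaling rules for both software styles
#' @return A named list of [rescale_rule()] objects keyed by software style.
#' @export
default_rescale_rules <- function() {
  list("SPM-like" = rescale_rule("SPM-like"),
       "FSL-like" = rescale_rule("FSL-like"))
}
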