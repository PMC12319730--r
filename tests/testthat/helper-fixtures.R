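# Small cohort builders used across tests. All fixtures are generated in
# code from seeds; nothing is read from disk.

tiny_grid <- function(n = 16L) volume_grid(c(n, n, n), voxel_size = 2)

# one-pipeline cohort at desk scale
tiny_cohort_config <- function(n_subjects = 40L, seed = 5L, n = 16L,
                               pipelines = NULL, ...) {
  if (is.null(pipelines))
    pipelines <- list(pipeline_spec("p1", "SPM-like", smoothing_fwhm = 5))
  cohort_config(n_subjects = n_subjects, pipelines = pipelines,
                grid = tiny_grid(n), seed = seed, ...)
}

# two pipelines identical except for the fields in `...` of the second
pair_cohort <- function(n_subjects = 60L, seed = 9L, n = 16L, gain2 = 1,
                        style2 = "FSL-like", ...) {
  cfg <- cohort_config(
    n_subjects = n_subjects, grid = tiny_grid(n), seed = seed,
    pipelines = list(
      pipeline_spec("a", "SPM-like", smoothing_fwhm = 5),
      pipeline_spec("b", style2, smoothing_fwhm = 5, gain = gain2, ...)))
  generate_cohort(cfg)
}
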