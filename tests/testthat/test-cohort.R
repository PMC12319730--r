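test_that("identity pipelines produce identical maps for a subject", {
  cfg <- cohort_config(
    n_subjects = 4L, grid = tiny_grid(12), seed = 11L,
    pipelines = list(
      pipeline_spec("u", "SPM-like", smoothing_fwhm = 4, unit_scale = 1),
      pipeline_spec("v", "FSL-like", smoothing_fwhm = 4, unit_scale = 1)))
  coh <- generate_cohort(cfg)
  expect_equal(coh$data[["u"]], coh$data[["v"]])
})

test_that("generation is bit-identical under one seed and differs under another", {
  cfg <- tiny_cohort_config(n_subjects = 5L, seed = 21L, n = 12)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$data, c2$data)
  cfg2 <- tiny_cohort_config(n_subjects = 5L, seed = 22L, n = 12)
  expect_false(identical(generate_cohort(cfg2)$data, c1$data))
})

test_that("unit scales 100 vs 2.5 give a voxelwise ratio of 40", {
  coh <- pair_cohort(n_subjects = 3L, n = 12)  # a: SPM 2.5, b: FSL 100
  common <- intersect_masks(coh$masks)
  keep <- which(common)
  for (s in coh$subject_ids) {      # brute-force voxel loop, per subject
    a <- coh$data[["a"]][keep, s]
    b <- coh$data[["b"]][keep, s]
    expect_true(all(abs(b / a - 40) < 1e-9))
  }
})

test_that("between-subject variance of the mean in-mask signal matches subject_sd^2", {
  cfg <- cohort_config(
    n_subjects = 500L, seed = 31L,
    grid = volume_grid(c(32L, 32L, 32L), voxel_size = 2),
    pipelines = list(pipeline_spec("p", "SPM-like", smoothing_fwhm = 5,
                                   unit_scale = 1)))
  coh <- generate_cohort(cfg)
  mask <- coh$masks[["p"]]
  means <- colMeans(coh$data[["p"]][which(mask), ])
  expect_equal(var(means), cfg$subject_sd^2, tolerance = 0.15)
})

test_that("null-map smoothness matches the quadrature target within 15%", {
  # gain = 0 pipelines carry pure noise; total FWHM^2 = noise^2 + kernel^2
  for (fwhm_mm in c(4, 6)) {
    cfg <- cohort_config(
      n_subjects = 30L, seed = 41L, grid = tiny_grid(24),
      noise_fwhm = 4, subject_sd = 0.1,
      pipelines = list(pipeline_spec("p", "SPM-like", gain = 0,
                                     smoothing_fwhm = fwhm_mm,
                                     unit_scale = 1)))
    coh <- generate_cohort(cfg)
    mask <- coh$masks[["p"]]
    V <- coh$data[["p"]][which(mask), ]
    R <- (V - rowMeans(V)) / sqrt(rowSums((V - rowMeans(V))^2) / (ncol(V) - 1))
    sm <- estimate_smoothness(R, mask)
    target <- sqrt(4^2 + fwhm_mm^2) / 2   # mm -> voxels at 2 mm
    expect_equal(mean(sm$fwhm_vox), target, tolerance = 0.15)
  }
})

test_that("write_cohort emits one file per map plus masks and a manifest that round-trips", {
  coh <- pair_cohort(n_subjects = 2L, n = 12)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh, dir)
  expect_equal(nrow(manifest), 2L * 2L)  # n_subjects x n_pipelines
  expect_length(list.files(dir, pattern = "^sub-.*\\.nii\\.gz$"), 4L)
  expect_length(list.files(dir, pattern = "^mask_.*\\.nii\\.gz$"), 2L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  row <- manifest[manifest$subject_id == 2 & manifest$pipeline_label == "b", ]
  m <- read_contrast_map(row$path, mask = file.path(dir, "mask_b.nii.gz"))
  orig <- get_contrast_map(coh, 2L, "b")
  expect_equal(m$values, orig$values, tolerance = 1e-6)  # float32 storage
  expect_identical(m$mask, orig$mask)
  expect_equal(m$grid$voxel_size, orig$grid$voxel_size)
})
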