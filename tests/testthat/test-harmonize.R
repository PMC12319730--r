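make_map <- function(values, grid, ...) contrast_map(values, grid, ...)

test_that("resampling onto the same grid is the identity", {
  g <- tiny_grid(12)
  set.seed(4)
  m <- make_map(array(rnorm(prod(g$shape)), g$shape), g)
  out <- resample_to_template(m, g)
  expect_equal(out$values, m$values)
})

test_that("spline resampling reproduces constants and linear ramps", {
  g <- volume_grid(c(16, 16, 16), voxel_size = 2, origin_offset = 0)
  # half-voxel-shifted target grid
  g2 <- volume_grid(c(16, 16, 16), voxel_size = 2, origin_offset = 1)

  cm <- make_map(array(3.25, g$shape), g)
  out <- resample_to_template(cm, g2)
  expect_true(all(abs(out$values[out$mask] / 3.25 - 1) < 1e-6))

  # analytic ramp in world coordinates as the oracle
  ramp <- function(grid) {
    w <- lapply(1:3, function(a) grid_axis_coords(grid, a))
    outer(outer(0.1 * w[[1]], 0.2 * w[[2]], `+`), -0.05 * w[[3]], `+`) + 0.5
  }
  rm <- make_map(ramp(g), g)
  out <- resample_to_template(rm, g2)
  expected <- ramp(g2)
  expect_lt(max(abs(out$values[out$mask] - expected[out$mask])), 1e-4)
  # the shifted grid's last plane lies outside the source FOV and is dropped
  expect_false(any(out$mask[16, , ]))
})

test_that("resampling with disjoint fields of view errors", {
  g <- tiny_grid(12)
  far <- volume_grid(c(12, 12, 12), voxel_size = 2, origin_offset = 1e4)
  m <- make_map(array(1, g$shape), g)
  expect_error(resample_to_template(m, far), "overlap")
})

test_that("rescaling maps raw software units to percent BOLD", {
  g <- tiny_grid(12)
  spm <- make_map(array(250, g$shape), g, units = "raw_pipeline_units")
  out <- rescale(spm, rescale_rule("SPM-like"))
  expect_equal(out$values[1], 100)        # 250 * 0.4
  expect_identical(out$units, "percent_BOLD")
  fsl <- make_map(array(10000, g$shape), g, units = "raw_pipeline_units")
  expect_equal(rescale(fsl, rescale_rule("FSL-like"))$values[1], 100)
  ident <- rescale(make_map(array(2, g$shape), g),
                   rescale_rule("SPM-like", factor = 1))
  expect_equal(ident$values, array(2, g$shape))
  expect_error(rescale(out, rescale_rule("SPM-like")), "double-scaling")
})

test_that("harmonization equalizes software styles and is idempotent", {
  coh <- pair_cohort(n_subjects = 3L, n = 12)  # same latent, 2.5x vs 100x
  h <- harmonize_cohort(coh)
  keep <- which(h$common_mask)
  expect_equal(h$data[["a"]][keep, ], h$data[["b"]][keep, ], tolerance = 1e-10)
  expect_true(all(vapply(h$units, identical, logical(1), "percent_BOLD")))
  # voxels outside the common mask are zeroed out of downstream arrays
  expect_true(all(h$data[["a"]][-keep, ] == 0))
  h2 <- harmonize_cohort(h)
  expect_equal(h2$data, h$data)
  expect_identical(h2$common_mask, h$common_mask)
  expect_true(any(grepl("rescale skipped", h2$log)))
})

test_that("harmonization requires a rescale rule for every pipeline", {
  coh <- pair_cohort(n_subjects = 2L, n = 12)
  expect_error(harmonize_cohort(coh, rules = default_rescale_rules()["SPM-like"]),
               "no rescale rule for pipeline 'b'")
})

test_that("t statistics are invariant to harmonization rescaling", {
  # the same-pipeline FPR is therefore identical pre- vs post-harmonization
  coh <- pair_cohort(n_subjects = 12L, n = 12)
  h <- harmonize_cohort(coh)
  mask <- h$common_mask
  keep <- which(mask)
  raw <- coh$data[["a"]][keep, ]
  harm <- h$data[["a"]][keep, ]
  t_raw <- two_sample_tmap(raw[, 1:6], raw[, 7:12], mask)
  t_harm <- two_sample_tmap(harm[, 1:6], harm[, 7:12], mask)
  expect_equal(t_raw$t, t_harm$t, tolerance = 1e-10)
})
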