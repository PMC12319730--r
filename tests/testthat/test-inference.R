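test_that("sample_groups draws disjoint groups reproducibly", {
  ga <- sample_groups(1:4, 2, seed = 1)
  expect_length(intersect(ga$group1_ids, ga$group2_ids), 0)
  expect_setequal(c(ga$group1_ids, ga$group2_ids), 1:4)
  expect_identical(sample_groups(1:100, 10, seed = 7),
                   sample_groups(1:100, 10, seed = 7))
  expect_error(sample_groups(1:10, 6), "too small")
})

test_that("subject inclusion frequency matches the binomial oracle", {
  pool <- 1:1080
  n_draws <- 10000L
  counts <- integer(1080)
  set.seed(13)
  for (i in seq_len(n_draws)) {
    ga <- sample_groups(pool, 50)
    idx <- c(ga$group1_ids, ga$group2_ids)
    counts[idx] <- counts[idx] + 1L
  }
  p <- 100 / 1080
  se <- sqrt(p * (1 - p) / n_draws)
  freq <- counts / n_draws
  # each subject's inclusion frequency within 3 SE of the binomial rate,
  # allowing the expected handful of 3-sigma exceptions among 1080 subjects
  expect_lt(mean(abs(freq - p) > 3 * se), 0.01)
  expect_equal(mean(freq), p, tolerance = 1e-12)
})

test_that("two-sample t matches the closed-form oracle on a single voxel", {
  # independent oracle: textbook pooled two-sample t computed by hand
  g1 <- c(1, 2, 3, 4); g2 <- c(5, 6, 7, 8)
  sp2 <- (3 * var(g1) + 3 * var(g2)) / 6
  t_oracle <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  mask <- array(FALSE, c(8, 8, 8)); mask[4, 4, 4] <- TRUE
  res <- two_sample_tmap(matrix(g1, 1), matrix(g2, 1), mask,
                         variance_mode = "pooled")
  expect_equal(res$t, t_oracle)
  expect_equal(res$t, -4.381780, tolerance = 1e-6)  # frozen oracle value
  expect_equal(res$df, 6)
  expect_equal(unname(stats::t.test(g1, g2, var.equal = TRUE)$statistic),
               res$t)
})

test_that("pooled df is n1 + n2 - 2 (= 98 for two groups of 50)", {
  mask <- array(TRUE, c(8, 8, 8))
  set.seed(17)
  X1 <- matrix(rnorm(512 * 50), 512)
  X2 <- matrix(rnorm(512 * 50), 512)
  res <- two_sample_tmap(X1, X2, mask, variance_mode = "pooled")
  expect_identical(res$df, 98)
  expect_identical(res$df_scalar, 98)
})

test_that("direction flips the sign of the whole map", {
  mask <- array(TRUE, c(8, 8, 8))
  set.seed(19)
  X1 <- matrix(rnorm(512 * 6), 512); X2 <- matrix(rnorm(512 * 6), 512)
  a <- two_sample_tmap(X1, X2, mask, direction = "group1_gt_group2")
  b <- two_sample_tmap(X1, X2, mask, direction = "group2_gt_group1")
  expect_equal(a$t, -b$t)
})

test_that("Welch equals pooled t for equal group sizes; df when variances equal", {
  mask <- array(TRUE, c(8, 8, 8))
  set.seed(23)
  X1 <- matrix(rnorm(512 * 10), 512); X2 <- matrix(rnorm(512 * 10), 512)
  w <- two_sample_tmap(X1, X2, mask, variance_mode = "welch")
  p <- two_sample_tmap(X1, X2, mask, variance_mode = "pooled")
  expect_equal(w$t, p$t)                       # equal n: same standard error
  w2 <- two_sample_tmap(X1, X1 + 1, mask)      # same spread in both groups
  expect_equal(w2$df, rep(18, 512))            # Satterthwaite -> n1+n2-2
})

test_that("zero-variance voxels are flagged and excluded from detection", {
  mask <- array(FALSE, c(8, 8, 8)); mask[1:2, 1, 1] <- TRUE
  X1 <- rbind(c(1, 1, 1), c(1, 2, 3))
  X2 <- rbind(c(1, 1, 1), c(2, 3, 4))
  res <- two_sample_tmap(X1, X2, mask)
  expect_true(res$undefined[1])
  expect_true(is.na(res$t[1]))
  expect_equal(res$n_undefined, 1L)
  det <- detect(res, 0)
  expect_equal(det$n_suprathreshold_voxels, 0L)  # only the defined voxel counted
})

test_that("null t values pooled over repetitions match Student df = 98 moments", {
  cfg <- cohort_config(n_subjects = 250L, seed = 43L, grid = tiny_grid(20),
                       pipelines = list(pipeline_spec("p", "SPM-like",
                                                      smoothing_fwhm = 5)))
  coh <- harmonize_cohort(generate_cohort(cfg))
  est <- run_experiment(
    experiment_config("p", "p", n_repetitions = 40, seed = 3,
                      variance_mode = "pooled", tvalue_stride = 37L), coh)
  tv <- est$pooled_t
  expect_gt(length(tv), 3000)
  ref_sd <- sqrt(98 / 96)
  expect_equal(mean(tv), 0, tolerance = 0.06)       # Monte-Carlo error bound
  expect_equal(sd(tv), ref_sd, tolerance = 0.05)
})
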