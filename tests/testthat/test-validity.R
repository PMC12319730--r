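test_that("acceptance region matches binomial quantiles", {
  # exact enumeration oracle for Binomial(2, 0.5): qbinom(.025) = 0,
  # qbinom(.975) = 2, so the region spans {0, ..., 1}
  expect_equal(unname(acceptance_region(0.5, 2)), c(0, 1))
  # large-n normal limit
  r <- acceptance_region(0.05, 1e6)
  lim <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 1e6)
  expect_equal(unname(r), lim, tolerance = 1e-3)
})

test_that("fpr_estimate verdicts follow the acceptance region", {
  e <- fpr_estimate(100, 1000)           # 0.1 > 0.064
  expect_identical(e$verdict, "invalid")
  expect_identical(fpr_estimate(50, 1000)$verdict, "valid")
  expect_identical(fpr_estimate(10, 1000)$verdict, "conservative")
  expect_true(e$wilson_ci[1] < e$rate && e$rate < e$wilson_ci[2])
})

test_that("an extreme pipeline difference is detected in a single repetition", {
  coh <- pair_cohort(n_subjects = 20L, n = 16, gain2 = 50)
  est <- run_experiment(
    experiment_config("b", "a", n_repetitions = 1, n_per_group = 10, seed = 2),
    coh)
  expect_equal(est$rate, 1)
  expect_true(est$records$any_detection[1])
})

test_that("experiments are reproducible from the seed and stable across seeds", {
  coh <- harmonize_cohort(pair_cohort(n_subjects = 120L, n = 16))
  cfg <- experiment_config("a", "b", n_repetitions = 30, seed = 5)
  e1 <- run_experiment(cfg, coh)
  e2 <- run_experiment(cfg, coh)
  expect_identical(e1$records, e2$records)
  cfg2 <- experiment_config("a", "b", n_repetitions = 30, seed = 6)
  e3 <- run_experiment(cfg2, coh)
  expect_false(identical(e1$records$group1_ids, e3$records$group1_ids))
  # same-pipeline-spec null: both rates near zero, differing at most by
  # binomial sampling error (3 SE at p = 0.05)
  expect_lt(abs(e1$rate - e3$rate), 3 * sqrt(0.05 * 0.95 / 30) + 1e-9)
})

test_that("a positive gain difference inflates only the favorable direction", {
  coh <- harmonize_cohort(pair_cohort(n_subjects = 150L, n = 20, gain2 = 1.5))
  up <- run_experiment(
    experiment_config("b", "a", n_repetitions = 40, seed = 8), coh)
  down <- run_experiment(
    experiment_config("b", "a", direction = "group2_gt_group1",
                      n_repetitions = 40, seed = 8), coh)
  expect_gt(up$rate, 0.5)
  expect_lt(down$rate, 0.15)
  expect_gte(up$rate, down$rate)
})

test_that("summarize_pairs reproduces the verdict invariant row by row", {
  coh <- harmonize_cohort(pair_cohort(n_subjects = 60L, n = 12))
  ests <- list(
    run_experiment(experiment_config("a", "b", n_repetitions = 5,
                                     n_per_group = 25, seed = 1), coh),
    run_experiment(experiment_config("a", "b",
                                     direction = "group2_gt_group1",
                                     n_repetitions = 5, n_per_group = 25,
                                     seed = 1), coh))
  tab <- summarize_pairs(ests)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$direction, c("group1_gt_group2", "group2_gt_group1"))
  for (i in seq_len(nrow(tab))) {
    expected <- if (tab$rate[i] > tab$region_high[i]) "invalid"
                else if (tab$rate[i] < tab$region_low[i]) "conservative"
                else "valid"
    expect_identical(tab$verdict[i], expected)
  }
  expect_equal(nrow(summarize_pairs(ests[1])), 1L)
})

test_that("experiments reject pools smaller than two groups", {
  coh <- pair_cohort(n_subjects = 8L, n = 12)
  expect_error(run_experiment(experiment_config("a", "b", n_repetitions = 1,
                                                n_per_group = 5, seed = 1),
                              coh),
               "pool")
})
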