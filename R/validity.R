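# Repeated between-group analyses for a pipeline pair and the empirical
# false positive rate with its binomial acceptance region.

#' Binomial acceptance region for an empirical false positive rate
#'
#' Central 95% region of `Binomial(n_repetitions, alpha) / n_repetitions`:
#' rates of a valid procedure fall inside it with 95% probability. With
#' `alpha = 0.05` and 1000 repetitions the region is (0.037, 0.064). Rates
#' above it indicate invalidity; below it, conservativeness.
#'
#' @param alpha nominal voxel-wise FWE level.
#' @param n_repetitions number of repeated between-group analyses.
#' @return Numeric `c(low, high)`.
#' @export
acceptance_region <- function(alpha, n_repetitions) {
  stopifnot(alpha > 0, alpha < 1, n_repetitions >= 1)
  # qbinom can return a tiny negative zero at the lower edge
  q <- pmax(0, stats::qbinom(c(0.025, 0.975), n_repetitions, alpha))
  c(low = q[1] / n_repetitions, high = q[2] / n_repetitions)
}

#' Configure a repeated between-group experiment
#'
#' @param pipeline1,pipeline2 pipeline labels; group 1 takes its maps from
#'   `pipeline1`, group 2 from `pipeline2`. They may be equal (same-pipeline
#'   baseline).
#' @param direction one-tailed test direction, `"group1_gt_group2"` or
#'   `"group2_gt_group1"`.
#' @param n_repetitions number of repetitions (1000 at paper scale; 200 is a
#'   desk-scale default for tests).
#' @param n_per_group subjects per group (default 50).
#' @param alpha voxel-wise FWE level (default 0.05).
#' @param seed integer seed driving all subject draws.
#' @param variance_mode `"welch"` (default) or `"pooled"`.
#' @param known_fwhm_vox optional per-axis FWHM (voxels) to bypass
#'   residual-based smoothness estimation.
#' @param tvalue_stride keep every `tvalue_stride`-th in-mask t value per
#'   repetition for pooled distribution diagnostics (0 disables).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(pipeline1, pipeline2,
                              direction = c("group1_gt_group2",
                                            "group2_gt_group1"),
                              n_repetitions = 1000L, n_per_group = 50L,
                              alpha = 0.05, seed = 1L,
                              variance_mode = c("welch", "pooled"),
                              known_fwhm_vox = NULL,
                              tvalue_stride = 100L) {
  direction <- match.arg(direction)
  variance_mode <- match.arg(variance_mode)
  stopifnot(n_repetitions >= 1, n_per_group >= 2, alpha > 0, alpha < 1)
  structure(list(pipeline1 = pipeline1, pipeline2 = pipeline2,
                 direction = direction,
                 n_repetitions = as.integer(n_repetitions),
                 n_per_group = as.integer(n_per_group), alpha = alpha,
                 seed = as.integer(seed), variance_mode = variance_mode,
                 known_fwhm_vox = known_fwhm_vox,
                 tvalue_stride = as.integer(tvalue_stride)),
            class = "experiment_config")
}

#' Estimate the pipeline-induced false positive rate
#'
#' For each repetition: draw two disjoint groups of subjects without
#' replacement, take group 1's maps from `pipeline1` and group 2's from
#' `pipeline2`, compute the one-tailed two-sample t map over the common
#' mask, solve the RFT voxel-wise FWE threshold (estimating smoothness from
#' the repetition's standardized residuals unless `known_fwhm_vox` is set),
#' and record whether any voxel is suprathreshold. The false positive rate
#' is the proportion of repetitions with at least one detection; since the
#' generative null holds (no group effect), detections are false positives.
#'
#' @param config an [experiment_config()].
#' @param cohort an `fmri_cohort` containing both pipelines; harmonized
#'   cohorts are used as-is, raw cohorts are harmonized first with default
#'   rules.
#' @return An object of class `fpr_estimate`: counts, `rate`,
#'   `acceptance_region`, Wilson `wilson_ci` for the empirical rate,
#'   `verdict` (`"invalid"` / `"valid"` / `"conservative"`), a
#'   per-repetition `records` data frame (max t, threshold, detection count,
#'   estimated FWHM, sampled ids) and `pooled_t` (thinned t values across
#'   repetitions).
#' @export
run_experiment <- function(config, cohort) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(cohort, "fmri_cohort"))
  for (p in c(config$pipeline1, config$pipeline2))
    if (!p %in% names(cohort$data)) stop("cohort lacks pipeline '", p, "'")
  if (!isTRUE(cohort$harmonized)) cohort <- harmonize_cohort(cohort)
  if (length(cohort$subject_ids) < 2L * config$n_per_group)
    stop("cohort pool smaller than two groups of ", config$n_per_group)

  mask <- cohort$common_mask
  rows <- which(mask)
  V1 <- cohort$data[[config$pipeline1]][rows, , drop = FALSE]
  V2 <- cohort$data[[config$pipeline2]][rows, , drop = FALSE]
  ids <- cohort$subject_ids

  smooth_known <- if (!is.null(config$known_fwhm_vox))
    known_smoothness(mask, config$known_fwhm_vox) else NULL

  nrep <- config$n_repetitions
  rec <- data.frame(repetition = seq_len(nrep), max_t = NA_real_,
                    t_threshold = NA_real_, n_detected = NA_integer_,
                    any_detection = NA, df = NA_real_,
                    fwhm_x = NA_real_, fwhm_y = NA_real_, fwhm_z = NA_real_,
                    group1_ids = NA_character_, group2_ids = NA_character_)
  pooled_t <- vector("list", nrep)
  keep_idx <- if (config$tvalue_stride > 0L)
    seq(1L, length(rows), by = config$tvalue_stride) else integer(0)

  with_preserved_seed({
    set.seed(config$seed)
    for (r in seq_len(nrep)) {
      res <- tryCatch({
        ga <- sample_groups(ids, config$n_per_group,
                            config$pipeline1, config$pipeline2)
        X1 <- V1[, match(ga$group1_ids, ids), drop = FALSE]
        X2 <- V2[, match(ga$group2_ids, ids), drop = FALSE]
        ts <- two_sample_tmap(X1, X2, mask,
                              variance_mode = config$variance_mode,
                              direction = config$direction)
        sm <- if (is.null(smooth_known))
          estimate_smoothness(ts$residuals, mask) else smooth_known
        th <- solve_threshold(config$alpha, ts$df_scalar, sm)
        dt <- detect(ts, th)
        list(ga = ga, ts = ts, sm = sm, th = th, dt = dt)
      }, error = function(e) e)
      if (inherits(res, "error"))
        stop("repetition ", r, " failed (seed ", config$seed, "): ",
             conditionMessage(res))
      rec$max_t[r] <- res$dt$max_t
      rec$t_threshold[r] <- res$th$t_threshold
      rec$n_detected[r] <- res$dt$n_suprathreshold_voxels
      rec$any_detection[r] <- res$dt$any_detection
      rec$df[r] <- res$ts$df_scalar
      rec$fwhm_x[r] <- res$sm$fwhm_vox[1]
      rec$fwhm_y[r] <- res$sm$fwhm_vox[2]
      rec$fwhm_z[r] <- res$sm$fwhm_vox[3]
      rec$group1_ids[r] <- paste(res$ga$group1_ids, collapse = ";")
      rec$group2_ids[r] <- paste(res$ga$group2_ids, collapse = ";")
      if (length(keep_idx))
        pooled_t[[r]] <- res$ts$t[keep_idx]
    }
  })

  n_det <- sum(rec$any_detection)
  fpr_estimate(n_detections = n_det, n_repetitions = nrep,
               alpha = config$alpha, config = config, records = rec,
               pooled_t = unlist(pooled_t))
}

#' Assemble a false-positive-rate estimate with verdict
#'
#' @param n_detections repetitions with at least one detection.
#' @param n_repetitions total repetitions.
#' @param alpha nominal FWE level the acceptance region is built around.
#' @param config,records,pooled_t optional provenance attached by
#'   [run_experiment()].
#' @return An object of class `fpr_estimate`.
#' @export
fpr_estimate <- function(n_detections, n_repetitions, alpha = 0.05,
                         config = NULL, records = NULL, pooled_t = NULL) {
  rate <- n_detections / n_repetitions
  region <- acceptance_region(alpha, n_repetitions)
  # Wilson score interval (prop.test's small-count chi-square warning does
  # not affect the interval itself)
  wilson <- as.numeric(suppressWarnings(
    stats::prop.test(n_detections, n_repetitions, correct = FALSE))$conf.int)
  verdict <- if (rate > region["high"]) "invalid"
             else if (rate < region["low"]) "conservative" else "valid"
  structure(list(n_repetitions = n_repetitions, n_detections = n_detections,
                 rate = rate, alpha = alpha, acceptance_region = region,
                 wilson_ci = wilson, verdict = verdict, config = config,
                 records = records, pooled_t = pooled_t),
            class = "fpr_estimate")
}

#' @export
print.fpr_estimate <- function(x, ...) {
  cat(sprintf(
    "<fpr_estimate> %d/%d detections: rate %.3f (Wilson 95%% CI %.3f-%.3f)\n  acceptance region [%.3f, %.3f] at alpha %g -> %s\n",
    x$n_detections, x$n_repetitions, x$rate, x$wilson_ci[1], x$wilson_ci[2],
    x$acceptance_region["low"], x$acceptance_region["high"], x$alpha,
    x$verdict))
  invisible(x)
}

#' Tabulate false-positive-rate estimates for pipeline pairs
#'
#' @param estimates a list of `fpr_estimate` objects (each with its config).
#' @return A long-format `data.frame` with one row per estimate: pipelines,
#'   direction, counts, rate, acceptance region, Wilson CI, verdict.
#' @export
summarize_pairs <- function(estimates) {
  if (inherits(estimates, "fpr_estimate")) estimates <- list(estimates)
  stopifnot(length(estimates) >= 1L)
  do.call(rbind, lapply(estimates, function(e) {
    cfg <- e$config
    data.frame(
      pipeline1 = if (is.null(cfg)) NA_character_ else cfg$pipeline1,
      pipeline2 = if (is.null(cfg)) NA_character_ else cfg$pipeline2,
      direction = if (is.null(cfg)) NA_character_ else cfg$direction,
      n_repetitions = e$n_repetitions, n_detections = e$n_detections,
      rate = e$rate,
      region_low = unname(e$acceptance_region["low"]),
      region_high = unname(e$acceptance_region["high"]),
      wilson_low = e$wilson_ci[1], wilson_high = e$wilson_ci[2],
      verdict = e$verdict, stringsAsFactors = FALSE)
  }))
}

#' Write a pair summary table to CSV and JSON
#'
#' @param summary a `data.frame` from [summarize_pairs()].
#' @param csv_path,json_path output paths (`NULL` skips a format).
#' @return Invisibly, the summary.
#' @export
write_pair_summary <- function(summary, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(summary, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
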