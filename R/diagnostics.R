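# Distributional diagnostics: Bland-Altman style P-P curves with Beta
# order-statistic bands, and comparison of pooled t values to the Student
# reference.

#' One-tailed p-values from pooled t statistics
#'
#' Converts t values to upper-tail p-values under the Student reference
#' distribution (default df 98, the pooled two-sample df for two groups of
#' 50).
#'
#' @param t_values numeric vector of t statistics, a `tstat_result`, or an
#'   `fpr_estimate` carrying pooled t values.
#' @param df_reference reference degrees of freedom (default 98).
#' @return Numeric vector of p-values.
#' @export
pvalues_from_tmaps <- function(t_values, df_reference = 98) {
  stopifnot(df_reference > 0)
  tv <- if (inherits(t_values, "tstat_result")) t_values$t
        else if (inherits(t_values, "fpr_estimate")) t_values$pooled_t
        else as.numeric(t_values)
  tv <- tv[is.finite(tv)]
  stats::pt(tv, df_reference, lower.tail = FALSE)
}

#' Bland-Altman P-P curve with Beta order-statistic bands
#'
#' Under the null, p-values are Uniform(0,1) and the k-th of N ordered
#' p-values follows Beta(k, N-k+1) with expected value `k/(N+1)`. The curve
#' plots, against `x = -log10(k/(N+1))`, the difference
#' `y = -log10(p_(k)) - x`; pointwise bands come from Beta quantiles at
#' `(1 - band_level)/2` and `1 - (1 - band_level)/2` mapped to the same
#' scale. Zero p-values are floored at 1e-300 before the log transform and
#' counted.
#'
#' @param pvalues numeric vector of p-values (N >= 10).
#' @param band_level pointwise band coverage (default 0.95).
#' @return A `data.frame` of class `pp_curve` with columns `k`,
#'   `expected_p`, `observed_p`, `x`, `y`, `lower_band`, `upper_band`;
#'   attributes `N`, `band_level`, `n_floored`.
#' @export
pp_bland_altman <- function(pvalues, band_level = 0.95) {
  p <- as.numeric(pvalues)
  p <- p[is.finite(p)]
  N <- length(p)
  if (N < 10L) stop("need at least 10 p-values")
  stopifnot(band_level > 0, band_level < 1)
  n_floored <- sum(p < 1e-300)
  p <- pmax(sort(p), 1e-300)
  k <- seq_len(N)
  expected <- k / (N + 1)
  x <- -log10(expected)
  y <- -log10(p) - x
  a <- (1 - band_level) / 2
  lower <- -log10(stats::qbeta(1 - a, k, N - k + 1)) - x
  upper <- -log10(stats::qbeta(a, k, N - k + 1)) - x
  out <- data.frame(k = k, expected_p = expected, observed_p = p,
                    x = x, y = y, lower_band = lower, upper_band = upper)
  attr(out, "N") <- N
  attr(out, "band_level") <- band_level
  attr(out, "n_floored") <- n_floored
  class(out) <- c("pp_curve", "data.frame")
  out
}

#' Plot a Bland-Altman P-P curve
#'
#' @param x a `pp_curve`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot.pp_curve <- function(x, ...) {
  df <- as.data.frame(x)
  ggplot2::ggplot(df, ggplot2::aes(x = x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower_band, ymax = upper_band),
                         fill = "grey80") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = y), colour = "#00557f") +
    ggplot2::labs(
      x = expression(-log[10] ~ "expected p-value"),
      y = expression(-log[10] ~ "observed" - -log[10] ~ "expected"),
      title = "Bland-Altman P-P plot",
      subtitle = sprintf("N = %d, %g%% Beta order-statistic bands",
                         attr(x, "N"), 100 * attr(x, "band_level"))) +
    ggplot2::theme_minimal()
}

#' Write a P-P curve to CSV
#'
#' @param curve a `pp_curve`.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_pp_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Compare pooled t statistics with their Student reference
#'
#' Reports mean, sd and skewness of the pooled t values against the
#' reference Student(df) moments (mean 0, sd `sqrt(df/(df-2))`), histogram
#' data with the reference density, and shift flags: mean shift when
#' `|mean| > 3 * SE`, variance shift when the sd ratio leaves [0.9, 1.1].
#'
#' @param t_values numeric vector (>= 1000 values), `tstat_result`, or
#'   `fpr_estimate` with pooled t values.
#' @param df_reference reference degrees of freedom (default 98).
#' @param n_bins histogram bins.
#' @return An object of class `stat_distribution_report`.
#' @export
stat_distribution_report <- function(t_values, df_reference = 98,
                                     n_bins = 60L) {
  tv <- if (inherits(t_values, "tstat_result")) t_values$t
        else if (inherits(t_values, "fpr_estimate")) t_values$pooled_t
        else as.numeric(t_values)
  tv <- tv[is.finite(tv)]
  if (length(tv) < 1000L)
    stop("need at least 1000 pooled statistic values")
  n <- length(tv)
  m <- mean(tv); s <- stats::sd(tv)
  skew <- mean((tv - m)^3) / s^3
  ref_sd <- sqrt(df_reference / (df_reference - 2))
  se_mean <- ref_sd / sqrt(n)
  sd_ratio <- s / ref_sd
  h <- hist(tv, breaks = n_bins, plot = FALSE)
  mids <- h$mids
  ref_density <- stats::dt(mids, df_reference)
  structure(list(n = n, mean = m, sd = s, skewness = skew,
                 reference_df = df_reference, reference_mean = 0,
                 reference_sd = ref_sd, sd_ratio = sd_ratio,
                 mean_shift_flag = abs(m) > 3 * se_mean,
                 variance_shift_flag = sd_ratio < 0.9 | sd_ratio > 1.1,
                 histogram = data.frame(mid = mids, density = h$density,
                                        reference_density = ref_density)),
            class = "stat_distribution_report")
}

#' @export
print.stat_distribution_report <- function(x, ...) {
  cat(sprintf(
    "<stat_distribution_report> n = %d t values vs Student(%g)\n  mean %.4f (ref 0)%s, sd %.4f (ref %.4f, ratio %.3f)%s, skewness %.4f\n",
    x$n, x$reference_df, x$mean,
    if (x$mean_shift_flag) " [MEAN SHIFT]" else "",
    x$sd, x$reference_sd, x$sd_ratio,
    if (x$variance_shift_flag) " [VARIANCE SHIFT]" else "", x$skewness))
  invisible(x)
}
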