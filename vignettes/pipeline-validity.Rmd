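---
title: "Estimating pipeline-induced false positive rates in fMRI group analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pipeline-induced false positive rates in fMRI group analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipefpr)
```

## The problem

Subject-level fMRI contrast maps depend on the processing pipeline that
produced them: the software package (with its own unit conventions and
templates), the smoothing kernel, the motion regressors, and the
hemodynamic response model all leave a fingerprint on the map. When a
between-group analysis compares a group processed one way against a group
processed another way — as can happen when pooling shared or multi-site
data — those fingerprints masquerade as group differences. `pipefpr`
quantifies the damage: it estimates the *empirical false positive rate*
(FPR) of the standard mass-univariate between-group analysis when the only
systematic difference between groups is the pipeline.

The estimator is a resampling loop. For a pipeline pair $(p_1, p_2)$ and a
pool of $N$ subjects, each repetition draws $2n$ subjects without
replacement (default $n = 50$ per group), takes group 1's maps from $p_1$
and group 2's from $p_2$, computes a voxel-wise one-tailed two-sample
$t$ map, thresholds it at the $\alpha = 0.05$ family-wise error (FWE)
level with random field theory (RFT), and records whether *any* voxel
survives. The FPR is the fraction of repetitions with at least one
detection. Because subjects are exchangeable between groups and no true
group effect exists, every detection is a false positive.

A rate estimated from $R$ repetitions is compared against the central 95%
region of $\mathrm{Binomial}(R, \alpha)/R$: with $R = 1000$ and
$\alpha = 0.05$ this is $(0.037, 0.064)$. Rates above the region indicate
that pipeline differences *invalidate* the analysis; rates below it
indicate conservative behavior. A Wilson score interval for the empirical
rate is reported alongside, since that is what a user needs to compare two
experiments.

## The synthetic cohort

Real multi-pipeline cohorts are large and access-restricted, so the
package ships a generative emulation that reproduces the *structure* the
analysis depends on, with every parameter explicit. For subject $i$ on the
acquisition grid:

$$L_i = \mathrm{gain}_p\,\mu + b_i + \sqrt{f_p}\,\varepsilon_i$$

* $\mu$ — the true effect field, a sum of hard spherical blobs in percent
  BOLD change (default: one central blob, 8 mm radius, 1% amplitude).
* $b_i \sim N(0, \sigma_b^2)$ — a scalar subject random effect applied
  over the whole brain ($\sigma_b = 0.1$% BOLD by default). A task
  contrast largely cancels global and session effects, so the residual
  spatially constant component is set an order of magnitude below the
  noise; a spatially varying subject-effect option (`subject_effect =
  "field"`) exists but defaults off. A large constant component would also
  turn the $t$ map into a random-intercept-plus-field mixture that a
  single-FWHM random-field model cannot describe.
* $\varepsilon_i$ — stationary Gaussian noise, white noise convolved to
  FWHM 4 mm and scaled to sd 0.8% BOLD.

A *pipeline* is a parametric transform of that latent acquisition:
additional Gaussian smoothing (`smoothing_fwhm`, default 5 mm), a
software-style unit scale (2.5× percent BOLD for SPM-like maps, 100× for
FSL-like maps), a gain on the true effect (emulating amplitude
mis-estimation by HRF or motion models — noise is estimated, not scaled,
so `gain = 0` yields pure-noise maps), an optional smooth additive bias
field, a noise-variance factor, its own grid, and its own eroded brain
mask. The same $(b_i, \varepsilon_i)$ realization underlies all pipelines
for subject $i$: pipelines transform one acquisition, they do not re-scan
the subject. How one subject's maps co-vary across pipelines is not
identifiable from published group-level results; the shared-latent-map
assumption is the modeling choice made here, and it is the most favorable
one for detecting pipeline effects (cross-pipeline differences are purely
systematic, not stochastic).

All smoothing is separable circulant (periodic) Gaussian convolution, so
generated fields are exactly stationary and kernel widths compose in
quadrature: a pipeline's output smoothness is
$\mathrm{FWHM}^2_{\text{total}} = \mathrm{FWHM}^2_{\text{noise}} +
\mathrm{FWHM}^2_{\text{pipeline}}$, which gives the tests an analytically
known target. Randomness uses one root seed with per-subject substreams
(`seed + 1000003 i mod 2^31-1`), so cohorts are bit-reproducible and
order-independent.

What the generator does *not* emulate: raw BOLD time series, first-level
GLM fitting, registration, non-stationary anatomical smoothness, heavy
tails, or spatially structured between-subject variability. Passing tests
therefore demonstrate that the *machinery* behaves correctly under its own
assumptions, not that any particular real dataset is valid or invalid.

## Harmonization

Maps from different pipelines live on different grids, masks and unit
scales. `harmonize_cohort()` applies, in order: third-order (natural
cubic) spline resampling onto a configurable template grid; intersection
of all pipeline brain masks into one common mask; zeroing outside the
common mask; and unit rescaling to percent BOLD, multiplying SPM-like maps
by $100/250 = 0.4$ and FSL-like maps by $100/10{,}000 = 0.01$. Masks are
resampled nearest-neighbour, and voxels whose interpolation would require
extrapolation outside the source field of view are dropped from the mask
rather than filled — spline ringing never enters the statistics. A
double-scaling guard makes rescaling an error on already-converted maps,
and harmonization is otherwise idempotent.

## Group inference and RFT thresholding

`two_sample_tmap()` computes $t = (\bar m_1 - \bar m_2)/\mathrm{se}$ per
in-mask voxel, with either the Welch unequal-variance standard error
(per-voxel Satterthwaite df; the default, since unequal group variances
are exactly what pipeline differences produce) or the pooled-variance
standard error with $\mathrm{df} = n_1 + n_2 - 2$ (= 98 at the default
group size, the Student reference used by the diagnostics). Both are
exposed deliberately: second-level software differs in how it handles
nonsphericity, and the difference should be testable rather than hidden.
Under Welch, a single thresholding df is needed; the median of the
per-voxel Satterthwaite df is used (at $n = 50$ per group it is within a
unit of 98; sensitivity is negligible). Voxels with zero variance in both
groups have no defined $t$; they are flagged, counted, and excluded from
detection rather than set to 0.

The FWE threshold solves $\mathbb{E}[\mathrm{EC}](u) = \alpha$ where the
expected Euler characteristic of the excursion set is
$\sum_{d=0}^{3} R_d\,\rho_d(u, \nu)$ with the standard unified EC
densities for Student fields. Smoothness is estimated per axis from the
variance $v$ of first spatial differences of standardized residuals,
$\mathrm{FWHM} = \sqrt{4\ln 2 / v}$ voxels. Each residual map is first
centred on its in-mask spatial mean and voxel rows are re-standardized:
a spatially constant per-subject component (a global offset) carries no
spatial information but would otherwise inflate the per-voxel residual sd
and bias the FWHM upward by ~20% under the default subject effect. With
centring the estimate matches the quadrature target within a few percent.

Resel counts follow the mask lattice: $R_3$ is the voxel count times
$\prod_a 1/\mathrm{FWHM}_a$ (so a cubic mask of side $s$ at isotropic
FWHM $f$ has exactly $(s/f)^3$ resels), $R_1$ and $R_2$ use edge and face
counts with boundary corrections that make them exact for boxes, and
$R_0$ is the lattice Euler characteristic. Root solving uses `uniroot` on
the decreasing branch starting at the uncorrected Student quantile, with
the solution verified to $10^{-8}$ on the $\alpha$ scale. Detection uses
the closed convention $t \ge u$.

Because transcribing EC densities is the classic failure mode, the test
suite requires agreement with a max-statistic Monte-Carlo oracle: 2000
independent Student fields (df 98) simulated at known smoothness must
yield a realized FWE within $[0.03, 0.07]$ at the solved threshold. One
subtlety: circulant-generated fields are periodic — they live on a torus
with no boundary — so the oracle threshold uses pure-volume resels
$(0, 0, 0, R_3)$. Including box-boundary terms there would overstate the
expected EC. At FWHM 4 voxels the realized rate sits near 0.04; the
residual deficit is lattice discreteness (the sampled maximum
underestimates the continuum maximum), the same effect that makes
voxel-wise RFT conservative in practice.

## Diagnostics

Beyond the binary verdict, two diagnostics summarize *how* a configuration
deviates. `pp_bland_altman()` draws the difference variant of the P-P
plot: for $N$ sorted p-values, the $k$-th order statistic of a uniform
sample follows $\mathrm{Beta}(k, N-k+1)$ with expectation $k/(N+1)$, and
the curve plots $y_k = -\log_{10} p_{(k)} + \log_{10}\frac{k}{N+1}$
against $x_k = -\log_{10}\frac{k}{N+1}$, with pointwise 95% bands from
Beta quantiles mapped to the same scale. The tail of interest (small
p-values) is stretched, and a valid configuration stays inside the bands.
Zero p-values are floored at $10^{-300}$ and counted. The Beta bands
assume independent p-values; spatially correlated voxel statistics
violate that, so the default feed is a thinned sample (every 100th in-mask
voxel, pooled across repetitions) and the thinning stride is a parameter.
Which values enter the plot is a genuinely open design choice;
pooled-thinned is the default, per-repetition curves are available by
slicing the records.

`stat_distribution_report()` compares pooled $t$ values against the
Student reference: mean (reference 0), sd (reference
$\sqrt{\nu/(\nu-2)}$, about 1.0104 at $\nu = 98$), and skewness, flagging
a mean shift beyond $3\,\mathrm{SE}$ or an sd ratio outside $[0.9, 1.1]$.

## Numerical and scale choices

* Default grid $32^3$ at 2 mm: the brain-shaped super-ellipsoid mask spans
  ~13,000 voxels and, at the default total smoothness of 3.2 voxels FWHM,
  ~400 resels — the same order as a real 2 mm whole-brain analysis, at
  desk-scale cost. A $91 \times 109 \times 91$ grid is a constructor call
  away for realism.
* Desk-scale experiment: 200 repetitions (about half a minute after a
  ~15 s cohort generation); 1000 repetitions is the documented full-scale
  configuration and scales linearly.
* The gain sweep used in the tests spans 1.0–1.5 because, at the default
  signal-to-noise (blob amplitude 1% BOLD against an effective per-voxel
  sd of ~0.4% after smoothing), a 15% amplitude difference begins to
  inflate the FPR and a 50% difference saturates it — the regime of
  interest on both sides of the acceptance bound.
* Threshold solver tolerance $10^{-12}$ on $t$, verified to $10^{-8}$ on
  $\alpha$; detection ties break toward detection ($\ge$); degenerate
  zero-variance voxels are excluded and logged; FWHM estimates below 1
  voxel warn that the RFT approximation is degraded but do not error.

## A worked example

```{r example, eval = FALSE}
library(pipefpr)

cfg <- cohort_config(
  n_subjects = 300,
  pipelines = list(
    pipeline_spec("spm-s5", "SPM-like", smoothing_fwhm = 5),
    pipeline_spec("fsl-s5-g", "FSL-like", smoothing_fwhm = 5, gain = 1.3)),
  seed = 7)
cohort <- harmonize_cohort(generate_cohort(cfg))

baseline <- run_experiment(
  experiment_config("spm-s5", "spm-s5", n_repetitions = 200, seed = 11),
  cohort)
crossed <- run_experiment(
  experiment_config("fsl-s5-g", "spm-s5", n_repetitions = 200, seed = 11),
  cohort)

summarize_pairs(list(baseline, crossed))

curve <- pp_bland_altman(pvalues_from_tmaps(crossed, df_reference = 98))
plot(curve)
```

The baseline (same pipeline in both groups) lands below or inside the
acceptance region; the crossed pair with a 30% gain difference lands far
above it, and its P-P curve escapes the Beta bands in the tail.

## Known limitations

* The cross-pipeline dependence model (shared latent acquisition) is an
  assumption, not an estimate; real pipelines also differ stochastically.
* Voxel-wise RFT on a discrete lattice is conservative at low smoothness;
  the package reports what the standard procedure reports, it does not
  correct the conservativeness.
* The Beta P-P bands are pointwise and independence-based; with spatial
  correlation they are descriptive, not simultaneous inference.
* Only one-tailed voxel-wise inference is implemented — no cluster-extent,
  peak, permutation, or FDR inference, and no mitigation methods
  (covariates, ComBat-style harmonization); those are downstream of the
  question this package answers.
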