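Package: pipefpr
Title: False Positive Rates of Multi-Pipeline fMRI Group Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how differences between subject-level fMRI
    preprocessing/analysis pipelines inflate the family-wise false positive
    rate of between-group mass-univariate analyses. Provides a seeded
    synthetic generator of multi-pipeline subject-level contrast maps,
    harmonization of heterogeneous maps onto a common grid, mask and unit
    scale, voxel-wise one-tailed two-sample t maps (Welch or pooled),
    random field theory family-wise error thresholding (smoothness
    estimation, resel counts, expected Euler characteristic threshold
    solving), a repeated-sampling estimator of the empirical false positive
    rate with its binomial acceptance region, and Bland-Altman style P-P
    diagnostics with Beta order-statistic confidence bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
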