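Package: gamharm
Title: Multi-Cohort Harmonisation and Normative Modelling via Hierarchical GAMLSS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits hierarchical distributional regression models (GAMLSS) with
    cohort-specific random intercepts on location, scale, skewness and kurtosis
    for bounded, non-Gaussian continuous features; removes cohort (batch)
    effects by centile-based quantile mapping back to the native measurement
    scale; emits normative deviation z-scores from the same fit; and validates
    batch removal and biological-signal preservation with a metric suite
    (cohort R-squared increment, mean pairwise Kolmogorov-Smirnov statistic,
    distributional-moment contrasts, Spearman age correlation, Cohen's d for
    sex, and data-retention accounting). Includes a seeded multi-cohort
    lifespan simulator with known ground truth, a sequential
    distribution-selection fallback (sinh-arcsinh, generalised gamma, normal),
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mgcv,
    readr
Config/testthat/edition: 3
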