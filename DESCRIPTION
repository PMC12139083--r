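Package: rarecross
Title: Statistical Methods for Small-Sample Longitudinal Cross-Over Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for two-period, two-sequence cross-over trials
    with few subjects and repeated assessments, as encountered in rare-disease
    research (e.g. Epidermolysis bullosa simplex, where outcomes are blister
    counts and ordinal pain/pruritus scores). Provides prioritized generalized
    pairwise comparisons (net benefit) with thresholds, stratification and
    permutation inference; rank-based relative treatment effects with the
    ANOVA-type statistic and a Box-type approximation; a cumulative-logit
    marginal model for ordinal scores fitted by generalized estimating
    equations with independence or heterogeneous-autoregressive working
    association and small-sample sandwich corrections; a Gaussian-copula
    synthetic trial generator together with permutation-based null
    construction and effect injection; a Monte-Carlo rejection-rate harness
    for type-I-error and power studies; and maximum-a-posteriori (empirical
    Bayes) estimation of individual random effects for mixed models, enabling
    individualized prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
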