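Package: qpcrquant
Title: Efficiency-Weighted Relative Quantification of qPCR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of quantitative real-time PCR (qPCR)
    threshold-cycle data using efficiency-weighted delta-Ct values, which
    generalize the Livak 2^-ddCt and Pfaffl methods. Provides amplification
    efficiency estimation from dilution-series standard curves with pairwise
    slope comparison, fold-change analysis by t-test for two-condition
    designs, ANOVA/ANCOVA and repeated-measures fold-change analysis with a
    calibrator level via linear mixed models, relative-expression analysis
    with compact letter display grouping, back-transformed lognormal standard
    errors and confidence limits, residual diagnostics, publication-style bar
    plots, a synthetic-data generator with known ground truth, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    emmeans,
    car,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
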