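Package: utilicit
Title: Health-State Utility Elicitation, Simulation and Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for direct health-state utility elicitation and its
    downstream analysis. Implements the rating-scale (RS), standard-gamble
    (SG, adaptive bisection titration) and time-trade-off (TTO) elicitation
    procedures used to value post-treatment health states in head and neck
    cancer; a synthetic-respondent simulator that emulates the statistical
    structure of interview data (beta-distributed latent utilities, SG
    distortion toward 1, gamble refusals); descriptive summaries, rankings
    and rank-concordance of elicitation methods, normal-approximation
    confidence intervals, Spearman and Wilcoxon association tests and LOWESS
    smoothing; an iterative t-based sample-size calculation for estimating a
    mean utility to a target margin of error; and quality-adjusted life-year
    (QALY) computation from utility-weighted survival segments. Ships an
    18-state SNOMED CT-coded health-state catalog and published summary
    tables as plain-text fixtures.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
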