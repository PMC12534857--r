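Package: pdacscreen
Title: Cost-Effectiveness of Biomarker-Based Pancreatic Cancer Screening in
    New-Onset Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus Markov cohort model for evaluating biomarker
    screening strategies for pancreatic ductal adenocarcinoma (PDAC) in people
    with new-onset diabetes against standard of care. Implements the screening
    cascade arithmetic (single type 3c diabetes biomarker, single
    cancer-specific biomarker, and their sequential combination), conversion of
    stage-specific median survival to annual death probabilities, discounted
    cohort traces accruing life-years, quality-adjusted life-years and costs
    under configurable accrual conventions, incremental cost-effectiveness
    statistics with net monetary benefit and dominance handling, one-way
    (tornado) and two-way deterministic sensitivity analysis, Monte Carlo
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves and head-to-head comparison, and an individual-level cohort
    microsimulation that serves as a brute-force oracle for the deterministic
    cohort expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
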