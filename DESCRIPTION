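Package: blockrar
Title: Familywise Error Rate Control for Block Response-Adaptive
    Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design, simulation and analysis of multi-arm clinical trials
    that allocate patients to experimental arms in blocks using
    response-adaptive randomization (RAR) while keeping the control
    allocation fixed. Implements a variance-matched reweighting of the
    usual z-statistic against a pre-specified auxiliary design, which
    guarantees strictly positive block weights and an exactly standard
    normal null distribution, so that closed testing (pooled closed
    z-test or Bonferroni-Holm) controls the familywise error rate.
    Includes Bayesian adaptive randomization, an adversarial
    error-inflator allocation rule and fixed randomization, Bonferroni
    alpha-spending interim monitoring, and a vectorized Monte-Carlo
    engine for operating characteristics (FWER and disjunctive power).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
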