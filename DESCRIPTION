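Package: shiftanp
Title: Analytic Network Process Prioritization of Shift-Work Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native implementation of the Analytic Network
    Process (ANP) for weighing and ranking occupational shift-work
    disorders across worker groups. Provides Saaty-scale pairwise
    comparison matrices with eigenvector priorities and consistency
    screening (CI, CR, and a Monte Carlo random consistency index),
    supermatrix assembly with cluster weighting and limit priorities,
    a desirability index for ranking shift alternatives, long-format
    questionnaire import with geometric-mean group aggregation, and a
    synthetic-respondent generator that emulates cohorts of hospital
    shift workers for end-to-end validation. Bundles the shift-work
    decision network (7 criteria, 20 sub-criteria, 3 shift
    alternatives) and the published group-level weights as fixtures.
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
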