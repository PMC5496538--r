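Package: ovibias
Title: Sex-Biased Oviposition Analysis for Gynodioecious Host Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing sex bias in nursery-pollinator oviposition and
    floral damage on gynodioecious plants, where female and hermaphrodite
    individuals coexist. Provides exact (Clopper-Pearson) binomial confidence
    intervals for reported proportions; generalized linear model fitting by
    iteratively reweighted least squares for binomial, quasi-binomial,
    Poisson and quasi-Poisson families with likelihood-ratio chi-square and
    quasi-likelihood F tests and backward model selection; stratified
    (within-population) permutation tests for flower-level sex bias and
    within-pair sign-flip permutation tests for age-matched flower pairs,
    both with exact small-sample enumeration; a synthetic-data generator
    emulating transect surveys, whole-plant monitoring and paired-flower
    collections of a two-sex plant population; and pipeline functions that
    assemble the full analysis into reproducible reports.
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
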