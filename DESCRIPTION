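Package: agespec
Title: Specification-Curve Analysis of Age Effects on Decision-Making
    Under Uncertainty
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates an age-heterogeneous individual-differences study of
    decision-making under uncertainty and analyses it with a multiverse
    approach.  Provides a synthetic cohort generator with configurable age
    and covariate effects and block-correlated outcomes, simulators and
    scoring routines for the Balloon Analogue Risk Task (BART) with linear
    and exponential reward balloons and for a structured 80-trial delay
    discounting task, an exhaustive specification-curve engine (age effect
    on every outcome under every covariate subset, fitted by ordinary least
    squares on standardized variables), a permutation-based test of the
    global significance of a specification curve, and pairwise-complete
    Pearson correlation networks with thresholded edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
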