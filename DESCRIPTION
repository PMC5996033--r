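Package: wamaze
Title: Weighted Attention Modelling of Multidimensional Discrimination
    Learning in the Plus Maze
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-by-trial modelling of rodent multidimensional
    discrimination learning in a four-arm plus maze with intra- and
    extra-dimensional set shifts.  Simulates the task and artificial
    agents, implements two learning models -- naive reinforcement
    learning over feature combinations (NRL) and a weighted attention
    model with dimension-specific decision weights (WAM) -- fits them to
    behavioral logs by maximum likelihood (per-day learning rates and
    attention weights, per-set inverse temperature), and compares them by
    an AIC-style score and within-day cross-validation.  Includes the
    descriptive behavioral analyses: daily success rates, learning
    criteria, choice-by-correct-arm matrices, early/late stage splits and
    cohort weight dynamics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
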