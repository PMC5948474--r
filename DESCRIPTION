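Package: raterirt
Title: Rater-Effect Item Response Models for Performance Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Polytomous item response theory models for ratings assigned by
    multiple raters to examinee performances on multiple tasks. Implements the
    many-facet Rasch model, generalized partial credit and graded response
    extensions with rater severity, consistency and range-restriction
    parameters, and a hierarchical rater model with a signal-detection rating
    stage. Models are estimated by Metropolis-within-Gibbs MCMC with
    expected-a-posteriori point estimates; model comparison uses AIC, WAIC,
    BIC and the log marginal likelihood. Includes synthetic rating-data
    generation, rater/task bias-injection transformations, judge-pair
    missingness designs, parameter-recovery and model-selection experiment
    runners, and descriptive statistics for rating data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
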