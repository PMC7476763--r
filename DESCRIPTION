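Package: arbihgf
Title: Arbitration Between Social and Individual Learning with
    Hierarchical Gaussian Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Behavioural modelling of advice taking in a binary lottery
    task where participants arbitrate between social advice and
    individually experienced outcome frequencies. Implements a two-branch
    hierarchical Gaussian filter over advice accuracy and card-colour
    probability, a precision-ratio arbitration response model for binary
    advice-taking choices and 1-10 point wagers, maximum-a-posteriori
    model inversion with Laplace-approximate log model evidence,
    random-effects Bayesian model selection with protected exceedance
    probabilities, a synthetic task-schedule and agent simulator, and a
    parameter-recovery analysis quantified by Cohen's f.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
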