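Package: dasev
Title: Differential Abundance Analysis for Zero-Inflated Mass-Spectrometry
    Data with Empirical Bayes Variance Shrinkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential abundance analysis for zero-inflated proteomic and
    metabolomic abundance matrices. Observed zeros (point mass values) are
    modelled as a mixture of biological zeros (a point mass with a logistic
    regression on covariates) and technical zeros (left-censoring of a
    lognormal abundance component at a per-feature detection limit). The
    per-feature variance is stabilised by empirical Bayes shrinkage towards a
    shared inverse-gamma prior whose hyperparameters are estimated from the
    whole feature ensemble by the method of moments. Covariate effects on the
    non-zero mean, the zero proportion, or both are tested with likelihood
    ratio tests and Benjamini-Hochberg adjustment. An unshrunk
    maximum-likelihood comparator with a fixed variance floor is included,
    together with a simulation framework for power and false discovery rate
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
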