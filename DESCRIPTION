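Package: rrtdm
Title: Multiple-Trait Multiple-Lactation Random Regression Test-Day Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genetic evaluation of dairy-cattle production traits with a
    multiple-trait, multiple-lactation random regression test-day model.
    Test-day milk, fat and protein records are modelled with herd-year-month,
    breed-season-stage and age-at-calving fixed effects plus additive-genetic
    and permanent-environmental random regressions on orthonormal Legendre
    polynomials of days in milk. The package builds the pedigree numerator
    relationship matrix and its sparse inverse, estimates the regression
    coefficient (co)variance matrices and residual variances by Gibbs
    sampling, solves the mixed-model equations by preconditioned conjugate
    gradient for 305-day breeding values, and derives daily and 305-day
    heritabilities, genetic and permanent-environmental correlations and
    genetic trends. A synthetic-data generator simulates pedigrees and
    test-day records from the same generative model for validation.
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
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    MASS,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
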