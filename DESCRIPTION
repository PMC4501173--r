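Package: ovarisk
Title: Segregation Analysis and Risk Prediction for Familial Ovarian Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the genetic susceptibility to ovarian cancer
    in families: pedigree input/validation, a mixed major-gene (BRCA1/BRCA2
    plus an optional hypothetical third gene) and polygenic incidence model
    with the polygene discretised by the hypergeometric approximation,
    cohort-specific baseline incidences constrained to population and
    carrier rates, Elston-Stewart peeling of the family likelihood with
    proband-conditioned ascertainment correction, maximum-likelihood model
    fitting with likelihood-ratio and AIC comparison, carrier-probability
    and future-risk prediction incorporating a polygenic risk score, and
    closed-form population risk-stratification arithmetic for lognormal
    polygenic risk. Includes a forward simulator of ascertained families
    for validation by simulation.
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
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
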