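Package: esmrel
Title: Variance Decomposition and Reliability for Dyadic Experience-Sampling Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generalizability-theory analysis of intensive longitudinal data
    from couples. Decomposes item-response variance from experience-sampling
    surveys (items nested in moments, crossed with days, for persons nested in
    couples) into 22 crossed and nested variance components plus residual
    error, derives reliability coefficients at four aggregation levels
    (between couples, between persons, within persons between days, within
    persons between moments), and computes scale intercorrelations at those
    levels by sequential multilevel centering. Includes an exact
    stratum-likelihood estimator for balanced designs, a mixed-model path for
    unbalanced data, a closed-form expected-mean-squares oracle, and a
    simulator that generates dyadic experience-sampling datasets with known
    variance components, latent between-scale correlations, and survey-level
    missingness.
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
    lme4,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
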