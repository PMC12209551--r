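Package: frailcure
Title: Penalized Weibull Mixture Cure Models with Gamma Frailty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Weibull mixture cure models with a multiplicative gamma
    frailty on the latency hazard and a logistic incidence (cure) component,
    designed for right-censored survival data with high-dimensional covariates
    in both model parts. Estimation is by a penalized EM algorithm with a
    multi-step adaptive elastic-net penalty on the high-dimensional
    coefficients, with a generalized monotone incremental forward stagewise
    (GMIFS) fitter as an alternative. Includes an inverse-CDF data simulator
    for the improper population survival function, cross-validation driven by
    a cure-adjusted concordance index, variable-selection and estimation-error
    metrics, and a prognostic risk score builder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    Rcpp,
    rlang,
    stats,
    survival,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
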