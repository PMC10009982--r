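Package: dicheff
Title: Dichotomization Efficiency for Skew-Normal Covariates in Randomized Trials
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the loss of precision in treatment-effect estimates
    from two-arm randomized trials when a skew-normal baseline covariate is
    dichotomized before covariate adjustment. Provides a self-contained
    skew-normal kernel (density, distribution, quantile, moments, truncated
    means, sampling), closed-form variances of the treatment-effect estimator
    under full, restricted and dichotomized-covariate adjustment, the
    dichotomization efficiency D and optimal cut-point tables, a Monte-Carlo
    trial simulator with a regression-slope estimator of D, and maximum
    likelihood fitting of skew-normal parameters to percentile summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
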