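Package: metavalid
Title: Statistical Validity Testing for Meta-Analysis and Tailored
    Meta-Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether the summary estimate from a random-effects
    meta-analysis or a covariate-tailored meta-regression is statistically
    valid for a new independent setting, using a leave-one-out
    cross-validation statistic (Vn) whose null distribution is a linear
    combination of one-degree chi-squared variables.  Provides REML fitting
    of the random-effects model, the classical heterogeneity toolkit
    (Cochran's Q, I-squared, typical standard error, prediction intervals),
    exact tail probabilities for quadratic forms in normal variables via
    the Ruben series with certified truncation error (plus
    characteristic-function inversion and Satterthwaite alternatives), two
    published case datasets as built-in fixtures, and a simulation harness
    for type-1-error and power studies of Vn and Q.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
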