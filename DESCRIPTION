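Package: asymuncert
Title: Asymmetric Measurement Uncertainty Intervals from In-House Validation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a mean curve and a constant-plus-proportional variance
    function from factorial in-house method-validation studies with known
    concentrations, using restricted maximum likelihood with non-negative
    variance components. From the fitted precision profile it constructs a
    prediction range and inverts it to obtain measurement uncertainty
    intervals for routine results, which become asymmetric under
    heteroscedasticity, alongside the classical symmetric y +/- U interval
    for comparison. Includes closed-form intervals for constant relative
    standard deviation, a lognormal variant, a simulation engine for
    factorial validation designs, and Monte Carlo coverage and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
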