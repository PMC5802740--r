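Package: repint
Title: Bayesian Prediction Intervals for Replication-Study P-Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs prediction intervals for the P-value of a replication
    study from a single observed test result. Implements the classical
    frequentist P-interval, a conjugate-normal Bayes interval for Z-statistics,
    and a Mixture Bayes interval that discretizes an arbitrary prior on the
    standardized effect size and averages noncentral predictive distributions
    (normal, Student t, chi-square, F). Includes standardized effect-size
    bounds for odds ratios, prior-variance estimation from tabulated
    odds-ratio distributions, and a Monte-Carlo engine that measures interval
    coverage under P-value selection (thresholds, windows, minimum of L tests)
    and prior mis-specification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
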