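Package: ahazpar
Title: Parametric Additive Hazard Models for Time-Constant Absolute
    Treatment Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits additive hazard models h_x(t) = h_0(t) + x*beta with a
    parametric baseline hazard (exponential, linear hazard rate, Weibull,
    log-logistic, Gompertz, Gamma-Gompertz, or piecewise constant) by
    maximum likelihood, for two-arm time-to-event data from randomized
    trials.  The treatment coefficient beta is a time-constant hazard
    difference; the package derives absolute effect measures from it:
    the rate difference per 1,000 person-years, the number needed to
    treat in person-years, distribution modes and mode differences, all
    with delta-method confidence intervals.  Also provides the
    semiparametric Lin-Ying additive hazards estimator, actuarial
    life-table hazards, Kaplan-Meier based time-dependent NNTs, and a
    simulator for two-arm additive-hazard trials with administrative and
    accrual censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    flexsurv,
    optparse
Config/testthat/edition: 3
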