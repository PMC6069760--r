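Package: plndsurv
Title: Causal Survival Analysis for the Extent of Pelvic Lymph Node Dissection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the effect of a count-valued "treatment" (the
    number of pelvic lymph nodes removed at prostatectomy) on right-censored
    outcomes in observational cohorts. Implements a beta-binomial model for
    nodal misclassification (the probability that a node-positive patient shows
    no positive node among those examined), a Poisson-regression propensity
    model for the number of nodes removed with group-level inverse-probability
    weights, weighted Kaplan-Meier and doubly-robust survival estimators built
    on per-group weighted Cox models, bootstrap confidence intervals for group
    survival probabilities and their differences, and a simulation harness that
    measures bias and root mean squared error of the unadjusted, weighted and
    doubly-robust estimators under propensity- and outcome-model
    misspecification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
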