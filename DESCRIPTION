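Package: fishmot
Title: Fish-Like Multiple Object Tracking Stimuli and Hierarchical Bayesian
    Signal Detection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying multiple object tracking (MOT) with
    naturalistic fish-like motion. Decomposes object trajectories into
    waiting and sudden-movement (dash) phases and fits gamma laws to the
    resulting motion parameters; simulates fish-like (wait/dash) and
    traditional ballistic MOT trajectories in a circular arena; enumerates
    counterbalanced tracking-experiment designs; generates synthetic
    observer responses from an equal-variance signal detection model with
    participant-level random effects; and estimates sensitivity (d') and
    bias via hierarchical Bayesian probit regression with condition
    contrasts, Savage-Dickey Bayes factors, cross-condition prediction
    models, and Bayesian R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rjags,
    MASS
Config/testthat/edition: 3
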