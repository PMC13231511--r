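Package: fightdyn
Title: Fight Dynamics from Line-Mounted Jerk Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies fish capture-event (fight) dynamics from tri-axial
    jerk accelerometers attached to fishing lines. Computes per-fish summary
    fight metrics (bursts, effort, intensity phases, fatigue index),
    dynamic-time-warping dissimilarities under twelve signal-processing
    variants, behavioural clusters via Ward agglomeration with gap-statistic
    selection, and Bayesian bivariate Gaussian regressions linking movement
    dimensions to post-capture blood pH and plasma lactate, with a
    thirteen-pipeline comparison by K-fold information criterion and
    Bayesian R-squared. Includes a seeded synthetic capture-event generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    coda,
    jsonlite,
    rjags,
    stats,
    utils,
    vegan
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
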