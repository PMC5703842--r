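Package: stnbart
Title: Simulation and Analysis of Subthalamic Activity in a Continuous
    Balloon Risk Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying subthalamic-nucleus electrophysiology
    recorded during a self-paced, continuous-time balloon analog risk
    task. Provides a synthetic-session generator (behaviour, spike
    trains, local field potentials), optimal-stopping analysis of the
    task, a regularized Poisson generalized linear model of single-unit
    firing, Hilbert band-power and Morlet time-frequency analysis with
    decibel baseline normalization, cluster-mass permutation statistics
    for time-frequency contrasts, and a discrete-time Bayesian
    proportional-hazards model with a horseshoe prior that predicts
    voluntary stop decisions from channel-by-band field-potential power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    signal,
    rjags,
    coda,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
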