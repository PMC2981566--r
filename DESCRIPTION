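Package: tvorsim
Title: Simulation and Model Fitting for the Translational Vestibulo-Ocular Reflex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the horizontal translational vestibulo-ocular
    reflex (tVOR) during interaural translation steps. Generates trapezoidal
    sled stimuli and synthetic binocular eye-velocity recordings, simulates a
    linear block model in which otolith-transduced head acceleration drives a
    direct pathway and a parallel acceleration-to-velocity integrator ahead of
    the common velocity-to-position neural integrator and ocular plant, and
    fits recorded eye velocity both to a delayed linear combination of head
    velocity and acceleration (robust regression with a latency grid search)
    and to the dynamic model by bounded Levenberg-Marquardt optimization.
    Includes slow-phase extraction by acceleration/jerk thresholds, parameter
    sensitivity sweeps, frequency-response simulation, and step-response
    comparisons with three previously published tVOR architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Matrix,
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
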