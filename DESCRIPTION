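Package: StateDelaySSA
Title: Stochastic Simulation of Multistep Reactions with State-Dependent
    Time Delay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Replaces a multistep chemical reaction chain by a single
    delayed reaction whose time delay is computed from the current system
    state. Provides exact chain ground truth (closed-form total copy
    number, ODE integration, Gillespie simulation), a Lambert-W closed form
    for the state-dependent delay together with its calibrated
    approximation, empirical delay measurement from exact simulations,
    re-calibration of the delay coefficients, a rejection delay stochastic
    simulation algorithm supporting elementary, constant-delay,
    distributed-delay and state-dependent-delay channels, ready-made models
    of mRNA degradation, cell-cycle regulated gene expression and a
    Michaelis-Menten metabolic pathway, and approximate Bayesian
    computation (rejection sampling) for fitting delay models to observed
    time series.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
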