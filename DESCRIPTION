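Package: echtfit
Title: Modified Gompertz Modeling of Electrochemical Therapy Tumor Growth Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal tumor-volume data from
    preclinical electrochemical therapy (EChT) studies with the modified
    Gompertz equation. Implements the two-stage per-animal fitting protocol
    (unperturbed Gompertz before treatment, current-perturbed model after),
    leave-one-out PRESS and fit-first-m MPRESS predictive diagnostics,
    shape-preserving Hermite interpolation of sparse caliper series, kinetic
    endpoints (doubling time, regression percentage, growth delay, PD/SD/PR/CR
    response classes and overall effectiveness) and a seeded synthetic-cohort
    simulator emulating the design of a multi-electrode direct-current study,
    so every stage of the pipeline is testable without confidential raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
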