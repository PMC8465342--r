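Package: ipkin
Title: Compartmental Models of Intraperitoneal Insulin Absorption and Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling plasma insulin kinetics after intraperitoneal
    (IP) insulin delivery in type 1 diabetes. Implements a battery of nine
    compartmental models (three linear IP absorption structures crossed with
    three descriptions of hepatic insulin extraction on top of a two-compartment
    whole-body insulin kinetics model), a Bayesian maximum a posteriori (MAP)
    estimator with log-normal priors and known-variance Gaussian measurement
    error, posterior precision (CV) of the estimates, a model assessment and
    selection protocol (runs test on weighted residuals, parameter precision,
    BIC), and a synthetic-data generator emulating a 24-h hospitalized
    open-loop basal-bolus study day for virtual-patient parameter-recovery
    experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
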