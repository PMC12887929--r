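Package: itspower
Title: Monte Carlo Power Analysis for Interrupted Time-Series Designs
    Analysed with ARIMA Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation-based power and sample-size calculations for
    interrupted time-series (ITS) studies analysed with ARIMA
    intervention models. Outcome series are generated under a fully
    specified data-generating process (ARMA errors, step, pulse or
    change-in-trend intervention, an optional AR(1) covariate and an
    optional deterministic or stochastic baseline trend), an ARIMA
    model with exogenous regressors is fitted to each replicate, and
    statistical power is estimated as the proportion of replicates in
    which the intervention coefficient is significant. Includes
    inversion of the power function to the minimal detectable effect
    at a target power, batch generation of power lookup tables over
    series-length by effect-size grids, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
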