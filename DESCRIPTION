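Package: p53dyn
Title: Excitable p53 Signaling Dynamics Driven by Stochastic DNA Damage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of pulsatile p53 signaling in single
    cells. Couples an exact stochastic simulation of DNA double-strand-break
    (DSB) induction and repair (isolated and complex breaks, time-varying
    break rate) to an excitable ordinary-differential-equation model of the
    ATM-p53-Mdm2-Wip1 network, and provides trajectory statistics for
    pulsatile time series: continuous-wavelet ridge-line pulse detection,
    smoothing-spline amplitude and width refinement, inter-pulse-interval
    distributions and Kullback-Leibler divergences. Includes generic
    negative-feedback and negative-plus-positive-feedback toy models with a
    numerical bifurcation scan and oscillation-onset classifier, cell-
    population ensembles with lognormal Wip1 expression heterogeneity, and a
    synthetic-data generator emulating live-cell microscopy recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
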