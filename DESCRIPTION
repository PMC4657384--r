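Package: stoqssa
Title: Validity Testing for the Stochastic Quasi-Steady-State Approximation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building matched full and QSSA-reduced biochemical
    reaction network models, simulating them deterministically (stiff ODE
    integration) and stochastically (exact Gillespie simulation with
    elementary or non-elementary Hill/Michaelis-Menten propensities), and
    testing whether a stochastic QSSA reduction can be trusted. The test
    measures the deterministic reduction error over a region of initial
    conditions covering the likely stochastic fluctuations (slow species:
    stationary mean plus or minus three standard deviations from the reduced
    model's own stochastic simulation; fast species: their entire physical
    range), so the full stochastic model never needs to be simulated. Ships a
    catalog of five example systems (genetic negative feedback, cooperative
    enzyme kinetics, a transcriptional oscillator with total and prefactor
    QSSA variants, a negative feedback loop with composite reductions, and a
    linear transcription-translation cascade) together with their closed-form
    stationary moments where available.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    pracma,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
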