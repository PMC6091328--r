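Package: nodestim
Title: Stochastic Hodgkin-Huxley Simulation of Electrical Tinnitus Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates a single Ranvier node of an auditory nerve fiber as a
    stochastic Hodgkin-Huxley membrane patch in which sodium and potassium
    conductances arise from Markov-chain tracking of finite channel
    populations.  Provides exogenous stimulation waveforms (kilohertz
    continuous-wave sine, Gaussian white noise, and their combination)
    coupled as membrane-potential perturbations, seeded ensemble simulation
    with spike detection, and an inactivation statistic quantifying the
    reduction of pathologically elevated spontaneous firing toward the
    physiologic rate.  Includes a deterministic (infinite-channel) reference
    model, a synthetic Poisson spike-train generator for testing the metrics
    layer, and orchestration of the full condition grid over patch areas,
    bias current densities, and stimulus settings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
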