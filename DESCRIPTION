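Package: evoplast
Title: Evolutionary Search for Synaptic Plasticity Rules in Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cartesian genetic programming (CGP) over symbolic synaptic
    plasticity rules, evaluated inside spiking-network simulations of three
    task families: reward-driven spike/no-spike classification with
    eligibility traces and reward baselines, error-driven teacher-student
    regression on membrane potentials, and correlation-driven detection of
    frozen-noise spike patterns with homeostatic STDP. Includes a mu+lambda
    evolution strategy with neutral search and phenotype-level fitness
    caching, fixed-step simulators for stochastic escape-noise and
    leaky integrate-and-fire neurons, and the published reference rules for
    each task family as built-in, testable objects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
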