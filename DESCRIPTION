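Package: thermospike
Title: Temperature Compensation of Spike Generation in Conductance-Based
    Neuron Models
Version: 0.1.0
Authors@R:
    person("Theo", "Brandt", email = "theo.brandt@posteo.net",
           role = c("aut", "cre"))
Description: Tools to analyse how the temperature dependence of ion-channel
    kinetics and peak conductances shapes the temperature robustness of
    firing rates in a type I (Connor-Stevens) spike-generation model.
    Provides the temperature-scaled model with fast fixed-step and adaptive
    integrators, f-I curve extraction with square-root fits, a full-factorial
    sweep over nine Q10 parameters scored by a normalized RMSD robustness
    metric, grid-based elementary-effects sensitivity analysis with
    dimensional-stacking visualization, action-potential energy budgets
    (sodium load, charge-separation efficiency, resting costs), closed-form
    Fisher-information measures of rate coding, reverse-engineering of a
    sigmoidal mechanotransduction stage, a synthetic intracellular-recording
    generator, and the statistical analysis of rate-level curves at two
    temperatures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
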