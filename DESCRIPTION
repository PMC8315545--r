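Package: protoflux
Title: Proteomics-Constrained Prediction of Metabolic Fluxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes the steady-state feasible flux space of a
    constraint-based metabolic model as a truncated multivariate Gaussian
    via Expectation Propagation, samples it exactly with null-space Gibbs
    and Hit-and-Run Markov chains, and selects the flux vector minimizing a
    posterior-density-weighted Euclidean distance to quantitative enzyme
    abundances mapped onto reactions through gene-protein-reaction rules.
    Includes a simulation framework relating enzyme abundances to fluxes
    through hyperbolic, linear and Hill kinetics for validating recovery of
    hidden fluxes, a null-space modular decomposition of the stoichiometric
    matrix for assessing proteome coverage of metabolic pathways, and
    generators for synthetic constraint-based models and proteomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    xml2
Suggests:
    ape,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
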