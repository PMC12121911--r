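Package: cbsd
Title: Cascading Bistable Switch Model of EMT with DLC1
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic simulation of the cascading
    bistable switch (CBS) gene circuit of TGF-beta driven
    epithelial-mesenchymal transition (EMT), extended with the tumor
    suppressor DLC1 (the CBSD model). Provides Hill-kinetics ODE and
    explicit reaction-network representations, steady-state and
    pseudo-arclength bifurcation analysis with saddle-node detection,
    Gillespie stochastic simulation of single cells and populations,
    model calibration against CBS reference trajectories and printed
    fold-change constraints (differential evolution with local polish,
    adaptive-Metropolis MCMC, correlation-based model reduction, local
    sensitivity analysis), RACIPE-style parameter ensembles, and
    generators for synthetic qPCR-style fold-change data. Model exchange
    via SBML Level 3 and PEtab-style tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
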