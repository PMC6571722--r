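Package: sfcopoly
Title: Flat-Histogram Monte Carlo for Flexible-Semiflexible Multiblock
    Copolymer Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-chain coarse-grained model of a flexible-semiflexible
    multiblock copolymer in an implicit selective solvent, with a stochastic
    approximation Monte Carlo (SAMC) flat-histogram sampler that accumulates a
    two-dimensional density of states over (non-valent contact energy, number
    of favorable stiff angles).  From the density of states the package
    computes canonical heat-capacity state diagrams, microcanonical caloric
    curves in the conformational (NVU) and total-energy (NVE) ensembles with
    first/second-order pseudo-phase-transition classification, and morphology
    observables with a hierarchical coil/globule classifier.  Independent
    desk-scale oracles (closed-form phantom-chain statistics, uniform
    chain-growth sampling, fixed-temperature Metropolis) validate the sampler.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
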