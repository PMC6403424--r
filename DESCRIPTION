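Package: toroidyn
Title: Kinetics of Heat-Fuelled Helical Polymerization of Supramolecular Toroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic and mean-field simulation of dissipative (out-of-equilibrium)
    helical polymerization of toroidal subunits fuelled by heat pulses. Implements a
    reaction network with heat activation and first-order relaxation, closed/open
    spiral interconversion, cooperative nucleation-elongation with chain-chain
    joining, and per-subunit relaxation driving random chain scission; an exact
    Gillespie stochastic simulation engine (compiled and pure-R reference
    implementations); a length-resolved mean-field master-equation twin; energy
    input protocols (single and repeated heat fuelling, UV quenches); observable
    proxies for circular dichroism, dynamic light scattering and cryo-TEM chain
    length statistics; deterministic helix and spherocylinder-vesicle geometry;
    parameter calibration against time-series data with identifiability checks;
    and a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    graphics,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
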