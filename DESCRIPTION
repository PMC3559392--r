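Package: thermoweight
Title: Thermodynamic Completion and Energy-Weighted Analysis of
    Genome-Scale Metabolic Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Completes the thermodynamic annotation of a constraint-based
    metabolic model by inferring unknown Gibbs formation energies of
    compounds and unknown Gibbs reaction energies by least squares over
    the stoichiometric matrix, adjusts standard reaction energies to a
    millimolar reference state, solves the flux balance analysis linear
    program, builds an energetically weighted reaction network whose edge
    weights are free-energy dissipation rates (weight = free-energy
    change x flux), and computes the cell's free-energy balance between
    internal chemistry and environmental exchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Metabolomics, SystemsBiology, Network, GraphAndNetwork
RoxygenNote: 7.3.3
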