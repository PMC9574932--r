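Package: grds
Title: Graph-Driven Reaction Discovery and Chemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic reaction discovery in discrete molecular
    graph space. Molecular bonding graphs are built from Cartesian
    geometries by a covalent-radius cutoff rule; reaction classes are
    applied as before/after bond-pattern edits under per-element valence
    constraints. Chemical reaction networks are grown by stochastic
    single-ended exploration, and reactant-to-product mechanisms are found
    by simulated annealing over discrete reaction/atom-index sequences
    scored with element-wise or permutation-invariant spectral cost
    functions. A graph-restraining potential back-transforms graphs into
    3D coordinates, and transition-state-theory rate utilities plus an
    exact Gillespie stochastic simulator characterize the kinetics of the
    resulting networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
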