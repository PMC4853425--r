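Package: fullerkit
Title: Analysis Toolkit for Protein-Fullerene Co-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational companion for protein-directed fullerene
    co-assembly studies. Builds idealized C60 (truncated icosahedron) geometry,
    expands crystallographic lattices by symmetry with a contact-based image
    retention rule, superposes structures (Kabsch) and searches disjoint-segment
    backbone motifs against structure databases with sequence-logo construction.
    Includes a minimal Lennard-Jones/Monte Carlo particle engine driving an
    alchemical double-decoupling free-energy cycle (soft-core coupling, Zwanzig
    estimation, harmonic-restraint standard-state correction, hysteresis
    diagnostics), global fitting of sedimentation-equilibrium profiles for
    tetramer-octamer self-association, Beer-Lambert stoichiometry and
    size-exclusion chromatography calibration, plus seeded synthetic-data
    generators with machine-readable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
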