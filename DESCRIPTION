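Package: evbscan
Title: Potential Energy Surface Scans, Semantic Scan Graphs, and
    Empirical Valence Bond Coupling Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for one-dimensional potential energy surface (PES)
    scans of molecular systems: parsing quantum-chemistry scan logs in a
    documented Gaussian-style dialect, an in-memory domain model with
    internal-coordinate validation, a semantic (RDF/Turtle) representation
    of scans linked to species and calculation records with the canonical
    federated query patterns, classical force-field energy evaluation for
    user-declared state topologies, and the numerical core of reactive
    force-field parametrization: empirical valence bond (EVB) two-state
    coupling calibration and Morse potential fitting against reference
    scan energies, with residual diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'evbscan-package.R'
    'constants.R'
    'format.R'
    'AllGenerics.R'
    'AllClasses.R'
    'geometry.R'
    'model.R'
    'gaussian-io.R'
    'kg-vocab.R'
    'kg-graph.R'
    'kg-mapping.R'
    'kg-query.R'
    'ffeval.R'
    'fitting.R'
    'synth.R'
    'cli.R'
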