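Package: gik
Title: GPCR-G Protein Interface Kit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural-analysis toolkit for modelling and validating
    receptor-G protein complexes of class A GPCRs. Provides generic residue
    numbering annotation (Ballesteros-Weinstein for receptors, CGN for Galpha
    subunits), residue-contact and hydrogen-bond occupancy profiling over
    multi-replicate trajectory ensembles, contact-conservation tables across
    complex sets, a restraint-selection workflow for receptor-Galpha docking,
    helix-axis and TM-opening geometry, GROMOS-style conformational clustering
    with medoid representatives, block-averaged RMSD statistics, and a
    synthetic-data generator that plants ground-truth contacts, hydrogen
    bonds, and conformational basins for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
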