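Package: esynth
Title: Graph-Based Fragment Synthesis of Target-Focused Screening Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes bioactive small molecules into rigid fragments and
    flexible linkers along rotatable bonds, consolidates the fragments into a
    non-redundant library with merged connectivity annotations, and exhaustively
    recombines them level by level under connectivity and drug-likeness
    constraints to enumerate target-focused virtual screening libraries.
    Includes Bloom-filter deduplication of canonical SMILES streams,
    fragment-additive estimation and linear calibration of Lipinski descriptors
    with a modified Rule-of-Five filter, fingerprint and maximum-common-
    substructure Tanimoto similarity, and self-benchmarking plus
    leave-one-cluster-out cross-validation protocols with a deterministic
    synthetic fixture generator. Chemistry input/output (SDF, SMILES, SYBYL atom
    typing, FP2 fingerprints, atomic-contribution logP) is delegated to Open
    Babel through ChemmineOB.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
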