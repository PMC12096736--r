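Package: mitoRCA
Title: Relative Complex Abundance Analysis for Mitochondrial Disease
    Proteomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Variant prioritisation support for suspected mitochondrial
    disease from untargeted label-free (DIA) proteomics. Implements
    cohort-specific missing-value and peptide-evidence filtering of
    protein quantity matrices, mitochondrial-content-corrected Relative
    Complex Abundance (RCA) of the OXPHOS complexes and mitoribosome with
    defect classification, single-protein range scoring against the
    control median, volcano statistics and fold-change correlation, gene
    panel coverage, benchmarking of RCA calls against respiratory chain
    enzymology (RCE) classified by Bernier-style criteria, and a seeded
    synthetic proteome simulator with complex co-regulation,
    mitochondrial-content shifts and abundance-dependent dropout for
    desk-scale validation of every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software, DifferentialExpression
RoxygenNote: 7.3.3
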