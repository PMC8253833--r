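Package: ctcflow
Title: Spatial Heterogeneity and Immune-Evasion Analysis of Circulating
    Tumor Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing full-length single-cell RNA-seq profiles of
    circulating tumor cells (CTCs) sampled from multiple vascular sites along
    the blood-flow route. Implements cell- and gene-level quality-control
    filters, a pairwise-correlation statistic of cell-to-cell transcriptional
    heterogeneity, G1/S and G2/M cell-cycle scoring with cycling/noncycling
    classification, a staged differential-expression marker cascade with
    Benjamini-Hochberg control, hypergeometric gene-set over-representation,
    expression-based copy-number inference against reference cells, and a
    transcription-factor-to-target correlation screen. A synthetic-cohort
    generator with full ground truth makes every stage testable without
    access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
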