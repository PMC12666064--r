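Package: celltox
Title: Cell-Type-Resolved Drug Toxicity Scoring and Pseudo-Bulk Dilution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for studying cell-type-mediated drug toxicity in
    single-cell RNA-seq data. Builds a unified drug-target-toxicity database
    from per-source target and label tables (logical-OR label merging),
    applies standard single-cell quality control, log-normalization and
    highly-variable-gene selection, computes per-cell drug scores as the
    mean expression of each drug's target genes, tests nephrotoxic versus
    non-nephrotoxic drug scores per cell type with FDR correction, and
    simulates multiplicative drug effects on a mediating cell type to
    quantify how pseudo-bulk averaging dilutes cell-type-confined toxicity
    signal relative to single-cell resolution. Ships a synthetic data
    generator (negative-binomial counts with a kidney-like cell-type
    composition, planted drug-target enrichment, and replicate-structured
    bulk signature matrices) so the whole pipeline is testable without
    external downloads, plus bulk differential-expression and toxicity
    classifier evaluation stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    graphics,
    yaml,
    pROC,
    ranger,
    xgboost,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
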