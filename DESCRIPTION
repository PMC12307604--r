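Package: methatlas
Title: Methylation Atlas Classification and Prognostic CpG Signatures for Acute Leukemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and applies a DNA-methylation reference atlas for acute
    leukemia from CpG beta-value matrices. Implements the full training
    pipeline (quality-control cascade, batch-mean imputation, empirical-Bayes
    batch correction, low-dimensional embedding, gradient-boosted subtype and
    five-year mortality classifiers, and a Cox-EWAS plus stability-selected
    CpG survival signature) and the inference path for both array-format
    methylomes and nanopore-derived bedMethyl files, including strand
    collapsing, discovery-mean imputation and confidence-gated reporting.
    Ships a synthetic-cohort generator so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    glmnet,
    jsonlite,
    rtracklayer,
    stats,
    survival,
    sva,
    utils,
    xgboost
Suggests:
    caret,
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
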