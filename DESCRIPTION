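Package: smokeSig
Title: Interaction Modeling and Signature Extraction for Smoke-Exposed
    Mouse Lung Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for distinguishing cigarette-smoke-related from
    spontaneously arising lung tumors in the A/J mouse from microarray
    expression data. Implements probe-level preprocessing (normexp
    background correction, quantile normalization, median or median-polish
    summarization, percentile-based detection calls, between-array
    correlation QC), a tissue-by-dose interaction linear model with
    per-feature OLS tests, contrasts and Benjamini-Hochberg FDR control, a
    resampling-based discriminative gene-signature extractor combining SAM
    ranking with linear support-vector machines, a contrast-based subset
    taxonomy for interaction-significant miRNAs, and seeded synthetic-data
    generators with planted ground truth for validating the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    e1071,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
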