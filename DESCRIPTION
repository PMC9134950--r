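Package: ferrolica
Title: Ferroptosis, Local Immune Cytolytic Activity and Tumor Microenvironment
    Scoring for Skin-Cancer Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for comparing ferroptosis-related gene (FRG)
    activity and local immune cytolytic activity (LICA) between tumor cohorts
    from bulk and single-cell expression data. Provides differential-expression
    screening with cross-dataset intersection, a from-scratch single-sample
    GSEA (ssGSEA) running-sum engine, scoring of immune and tumor
    microenvironment (TME) metabolic gene-set collections, the ferroptosis
    potential index (FPI), the overall-score-share (OSS) statistic with its
    correlation-connected (ccOSS) gene-set network, and a single-cell
    cytolytic-activity stage, plus bulk and single-cell simulators that
    generate data with known planted structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
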