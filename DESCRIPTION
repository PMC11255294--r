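Package: plasticore
Title: Single-Nucleus Multiome Analysis of Innate Lymphoid Cell Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for paired single-nucleus RNA and ATAC
    (multiome) data centred on innate lymphoid cell (ILC) lineage
    plasticity. Provides nucleus-level quality control, library-size
    log-normalization and TF-IDF peak normalization, Wilcoxon rank-sum
    differential testing with AUC effect sizes, per-cell signature
    scoring and rank-based cell-type classification, chromVAR-style
    motif deviation z-scores, combined RNA-and-motif candidate
    regulator ranking, gene-body accessibility scores, a simplified
    negative-binomial Wald test for replicated bulk accessibility, and
    per-nucleus scoring of pooled patient samples at signature region
    sets. A synthetic multiome generator with planted ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
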