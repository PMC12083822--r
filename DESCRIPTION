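Package: epidrugscreen
Title: Epigenetic Drug Screen Analysis with Co-Expression and Chromatin
    Accessibility Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-timepoint epigenetic drug screens in
    patient-derived tumor sphere cultures: delta-AUC viability statistics and
    compound-class rank aggregation, four-parameter logistic IC-50 fitting,
    fold-change gene-set derivation from RNA-seq counts, cross-line and
    cross-drug gene-set overlap consistency analysis, baseline-transcriptome
    clustering with drug-sensitivity association, weighted co-expression
    module detection (soft threshold, topological overlap, average-linkage
    modules) with module-drug effect scoring, and control-vs-treated ATAC
    peak-set comparison. A synthetic-data generator with planted ground truth
    provides recovery-based tests for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    DESeq2
Config/testthat/edition: 3
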