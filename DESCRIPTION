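Package: osccfitness
Title: Fitness-Gene Discovery from Pooled CRISPR Knockout Screens in Oral
    Cancer Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for genome-wide pooled
    CRISPR-Cas9 fitness screens in cancer cell line panels, modelled on the
    analysis of oral squamous cell carcinoma (OSCC) dependency screens.
    Provides median-ratio count normalization, plasmid-representation
    filtering, segmentation-based correction of copy-number-driven
    depletion bias, quantile and empirical-Bayes batch normalization into
    per-gene CRISPR scores, a rank-aggregation depletion test with a
    permutation null, a context-specific fitness catalogue built by
    expression and core-fitness filtering, dependency gene-expression
    signature scoring and classification of tumor cohorts, and
    single-sample / pre-ranked gene set enrichment. A synthetic-data
    generator with planted essential genes, copy-number segments and
    expression groups makes every stage verifiable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    sva,
    mclust,
    withr
Config/testthat/edition: 3
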