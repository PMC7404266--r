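Package: tsmeth
Title: Tissue-Specific Gene Expression and Promoter Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated analysis of tissue-specific gene expression and
    promoter DNA methylation across matched multi-tissue samples. Derives
    strand-aware promoter regions (proximal, typical, expanded) from GTF
    gene annotation, computes the Tau tissue-specificity statistic on
    per-tissue mean TPM, aggregates per-CpG whole-genome bisulfite
    methylation calls to promoter-region means, correlates expression with
    promoter methylation and classifies coupling direction, clusters
    methylation patterns, runs a local hypergeometric over-representation
    test against GMT gene sets, and performs a region-restricted
    epigenome-wide association study with Bonferroni discovery, independent
    replication and a covariate-adjusted secondary-trait test. A synthetic
    multi-omics generator with planted effects exercises the whole pipeline
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
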