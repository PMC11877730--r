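Package: xcimeth
Title: X Chromosome Methylation Analysis and X-Inactivation Escape Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing X chromosome DNA methylation array data in
    relation to X-chromosome inactivation (XCI), with an emphasis on tissues
    such as the placenta where the inactive X is hypomethylated. Provides
    genomic annotation of CpGs (promoter-, enhancer- and gene-body
    assignment, CpG-island density classes, partially methylated domains,
    repeat families), probe quality-control filtering, intensity-based sex
    inference, region-level per-sex beta-value summaries, an allele-balance
    XCI status classifier, a methylation-XCI correlation battery, scaled PCA
    with covariate association and PC-PR2 variance partitioning, per-CpG
    linear models with effect-size gating, and a synthetic-data generator
    that emulates active/inactive X methylation mixtures for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
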