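Package: cnvpop
Title: Population Analysis of Copy Number Variation Regions from Multi-Caller CNV Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for population-scale analysis of copy number variation
    (CNV) from per-sample, per-caller structural-variant calls. Implements
    quality filtering of read-depth CNV calls, cross-caller consensus merging
    by reciprocal overlap, construction and classification of copy number
    variation regions (CNVRs) across a cohort, read-depth copy-number
    genotyping, genomic context and QTL annotation, hypergeometric gene-set
    enrichment, and pairwise Vst divergence scanning with outlier calling.
    Includes a synthetic multi-population cohort generator with known ground
    truth for end-to-end validation.
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
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
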