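Package: smallRNAome
Title: Small RNA-Seq miRNAome Quantification, Discovery and Temporal Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis toolkit for
    developmental miRNAome studies. Implements read cleaning and collapsing,
    hierarchical annotation of unique tags (non-coding RNA filtering, tolerant
    known/edited/cross-species homolog miRNA matching, genome mapping and
    feature overlap), reads-per-million quantification with abundance tiering,
    genomic miRNA cluster detection, upper-quartile-scaled negative-binomial
    exact tests for stage-wise differential expression, model-profile
    clustering of short time-series trajectories with permutation
    significance, a simplified two-detector consensus caller for novel miRNA
    hairpins, and seed-match target prediction with expression
    anti-correlation filtering and gene-set enrichment. A self-consistent
    synthetic data generator with planted, recoverable truths supports
    benchmarking of every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    stringi,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
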