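Package: derseg
Title: Annotation-Free Detection of Differentially Expressed Regions by
    Changepoint Segmentation of RNA-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers differentially expressed regions (DERs) between two
    biological conditions from stranded RNA-seq alignments without requiring
    an annotation. Per-base coverage profiles are summarised into a per-base
    log2 fold-change signal, segmented exactly by functional-pruning optimal
    partitioning (FPOP) under a Gaussian mean-shift model, and each segment
    is tested with a negative-binomial Wald test. Benjamini-Hochberg
    adjustment and a Simes-family post-hoc bound on the false discovery
    proportion support DER calling at a user-chosen fold-change threshold.
    Includes annotation of DERs relative to their nearest features,
    genome-browser exports (BED, GFF3, bedGraph, IGV session XML), a
    synthetic-data generator with planted DERs, and label-based evaluation
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
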