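Package: isoscope
Title: Transcript-Level Interpretation of RNA-Seq Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream interpretation toolkit for transcript-level RNA-seq
    differential expression results. Builds transcript-to-gene dictionaries
    from GENCODE-style references (FASTA headers, GTF, GFF3), applies
    biotype-aware significance thresholds, detects isoform-switch candidates
    (significant transcripts whose parent genes are not significant), expands
    gene-level GMT gene sets to transcript sets stratified by transcript
    biotype and runs a natively implemented preranked enrichment with a
    permutation null, and builds declarative, backend-agnostic plot models
    for fold-change profiles, expression profiles and genomic-context
    (exon/intron) displays. A seeded simulator generates GENCODE-like
    fixtures with planted isoform switches for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ggplot2,
    rlang,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
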