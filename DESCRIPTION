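Package: graftmobile
Title: Detection of Graft-Mobile Small RNAs from Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA-seq analysis pipeline for grafted
    plants with sequence-diverged graft partners. Implements read
    preprocessing (adapter trimming, length and complexity filtering,
    exact-match decontamination), exact-occurrence read placement on a
    reference genome, coverage-island small RNA cluster calling with
    dicer-call scoring and size-class assignment, SNP-discriminative
    two-step classification of reads as native or graft-mobile, genomic
    annotation and cross-set comparison of clusters, Fisher-exact term
    enrichment, and ungapped local-alignment scoring of candidate target
    regions weighted by query coverage. A synthetic heterograft data
    generator with full ground truth (SNP table, planted loci, per-read
    provenance) makes every stage testable without external sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
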