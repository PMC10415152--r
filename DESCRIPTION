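Package: alnqc
Title: Mismatch-Centric Quality Control of Paired-End Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment quality control for coordinate-sorted paired-end
    BAM files. Re-walks every read against the reference genome to build
    per-cycle substitution profiles, substitution-category spectra with base
    quality and flanking-context distributions, and read-mismatch-content
    histograms, all stratified by read-pair orientation (read1/read2 crossed
    with forward/reverse strand). Includes multi-sample hierarchical
    clustering and outlier detection on QC feature matrices (Euclidean
    distance, Ward linkage, substitution-pair-deviation metric, Dixon's Q
    test), exon-level depth-of-coverage profiling, site-level pileup
    interrogation, extraction of read pairs with atypical mapping (long
    inserts, inter-chromosomal mates, anomalous orientation), a logistic
    site-confidence model for flagging low-confidence variant sites, and a
    deterministic synthetic-BAM fixture generator with exhaustive truth
    tables so every analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Rcpp,
    Rsamtools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    stats,
    utils,
    jsonlite,
    generics,
    methods,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
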