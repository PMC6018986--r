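Package: orgdriver
Title: Driver Transcription Factor Discovery from Multi-Omic Organoid Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis toolkit for cell-type-enriched organoid
    multi-omics: spike-in anchored absolute quantification of proteins (UPS2-style
    two-stage iBAQ regression) and transcripts (ERCC-style regression),
    protein-copies-per-mRNA ratio statistics with a replicate-restricted t-test,
    permutation-FDR moderated differential testing, median-of-ratios normalized
    shrunken fold changes for peak count matrices, TAD-level coordinated-activity
    detection with a shuffle null, preranked gene set enrichment with gene-set
    permutation FDR, and an iterative LASSO plus random-forest motif selection that
    identifies driver transcription factors from differential chromatin signal.
    A seeded synthetic-study generator plants known ground truth (true copy
    numbers, a driver motif, coordinated TADs, ratio-shifted genes) so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    glmnet,
    randomForest,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
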