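Package: contrastPeaks
Title: Replicate-Aware Contrastive Peak Calling for ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised peak calling for ATAC-seq (and related coverage
    assays) from multiple biological replicates. Candidate regions are
    extracted from per-replicate fragment coverage by a threshold-merge-filter
    procedure, fixed-length coverage segments are embedded with a dilated
    convolutional ResNet encoder trained under three jointly minimised losses
    (a cross-replicate contrastive loss, a segment-class contrastive loss and
    an autoencoder reconstruction loss), and peaks are called from averaged
    per-replicate peak-class probabilities. Includes evaluation utilities
    (overlap-weighted score transfer to labeled regions, precision/recall/F1,
    precision-recall curves and PRAUC, and a label-noise recall
    decomposition) and a synthetic multi-replicate fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    GenomeInfoDb
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
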