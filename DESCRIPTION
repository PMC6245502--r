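Package: squiggleplex
Title: Signal-Space Demultiplexing of Barcoded Nanopore Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for sorting Oxford Nanopore sequencing reads into
    barcode bins directly from the raw electrical current signal, without
    basecalling. Provides a squiggle simulator with known barcode ground
    truth (k-mer pore model, geometric dwell times, open-pore padding,
    cross-barcode chimeras), semi-global dynamic time warping for locating
    barcode signals inside reads, harvesting of labelled 1024-sample
    training windows with temporal-distortion augmentation and cross-split
    label refinement, a compact one-dimensional convolutional neural
    network classifier (convolution/max-pool groups, an inception-style
    parallel module with low-dimension bottlenecks, batch normalisation,
    dropout, a training-only Gaussian noise layer and global average
    pooling), multi-window read classification with max-then-renormalise
    probability merging, a probability-gap calling rule and chimera
    detection, and demultiplexing evaluation (confusion matrices,
    precision/recall, q-score stratified metrics and consensus binning).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
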