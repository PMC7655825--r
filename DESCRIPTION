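Package: scopekit
Title: Optically Decodable Bead Barcodes and Image-Linked Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for microwell single-cell RNA-seq with
    optically decodable mRNA capture beads. Designs two 96-member pools of
    8-nt cell barcodes with edit-distance, homopolymer, GC and
    self-complementarity constraints and maps them to 8-bit binary codes read
    out by sequential two-color fluorescent probe hybridization; decodes bead
    barcodes from 8-cycle x 2-channel intensity tables by population
    (cycle-by-cycle) and per-bead sorted fold-change (bead-by-bead)
    algorithms; detects microwells, cells and beads in images and extracts
    sixteen morphological and intensity features per cell; parses barcoded
    reads, corrects substitution errors, trims poly(A) tails and collapses
    unique molecular identifiers into a molecule count matrix; registers
    decoding images to live-cell images and links imaged cells to expression
    profiles; and provides downstream calling procedures (bimodal Gaussian
    thresholds, dead-cell filtering, factor-model imputation, aneuploidy-based
    malignancy scoring, imaging meta-features, subsampled Mann-Whitney
    differential expression). A simulator generates every input with ground
    truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    igraph,
    tiff,
    png,
    optparse
Config/testthat/edition: 3
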