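Package: kdeseq
Title: Adaptive-Bandwidth Kernel Density Signal Reconstruction for Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Track", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs genome-wide signal densities from mapped single-end
    sequencing reads (e.g. ChIP-seq) by kernel density estimation over integer
    base-pair positions. Supports fixed bandwidths and per-read adaptive
    bandwidths assigned by k-nearest-neighbor rules (including a variant that
    guarantees a strictly positive density between reads), three truncated
    kernel shapes (Gaussian, square, triangle) with discrete sum-to-one
    normalization, blending with a uniform genomic background, held-out
    likelihood tuning of the smoothing parameter on a 50/25/25 split, strict
    local-maxima analysis, exact piecewise track representations, and
    browser-ready bedGraph/WIG output. Includes a synthetic read simulator
    with known ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
Imports:
    BiocGenerics,
    GenomeInfoDb,
    GenomicAlignments,
    Rcpp,
    jsonlite,
    stats,
    utils
Suggests:
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
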