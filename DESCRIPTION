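Package: rloopgrammar
Title: Probabilistic Formal Grammar Modelling of R-Loop Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains and applies a probabilistic regular grammar for
    co-transcriptional R-loop formation on plasmid gene regions. Single-molecule
    R-loop footprints (BED intervals on a plasmid sequence) are converted into
    words over a ten-letter alphabet describing local duplex state and
    stability; production-rule probabilities are estimated from the words; and
    the fitted grammar predicts the per-nucleotide probability that each
    position of the gene region lies inside an R-loop, with ensemble means and
    standard errors over subsample-trained models. Includes k-mer weighting
    with entropy-based thresholding, union-dictionary construction across
    plasmids, three-fold cross-validation over the (k, p) parameter grid, and a
    synthetic-data generator with planted initiation/termination motifs for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
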