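Package: senoscore
Title: Senescence Scoring of Single Cells with a Zero-Inflated Negative
    Binomial Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns each cell (or spatial spot) in a single-cell RNA-seq
    count matrix a continuous senescence score using an unsupervised
    zero-inflated negative binomial (ZINB) autoencoder with a two-neuron
    bottleneck whose neurons are decorrelated by a Pearson-correlation
    penalty. Includes consensus curation of published senescence gene
    sets, optional ZINB-autoencoder denoising, score binarization via a
    per-cell permutation null combined with a Gaussian mixture model,
    evaluation statistics (AUROC, accuracy, F1, old/young enrichment),
    a targeted-panel subsetting utility, and a seeded synthetic ZINB
    data generator with known senescence ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    mclust,
    jsonlite,
    tibble,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
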