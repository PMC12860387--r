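Package: spotmix
Title: Multimodal Autoencoder Deconvolution of Spatial Transcriptomics Spots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates per-spot cell-type proportions in spot-based spatial
    transcriptomics by jointly learning from pseudo-spots simulated out of a
    single-cell reference, a k-nearest-neighbour spatial graph over real spots,
    multi-scale histology patch embeddings, an auxiliary spot-pathology
    classifier, and an adversarial domain matcher with a gradient reversal
    layer. Ships the pseudo-spot and tissue-slide simulators, in-silico
    histology artifact perturbations, global-statistics SSIM / Pearson / RMSE
    evaluation, a k-fold benchmarking protocol, and a small tape-based
    reverse-mode automatic differentiation engine that trains the multitask
    autoencoder on a single CPU.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
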