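Package: alphadose
Title: Small-Scale Alpha-Particle Dosimetry from Digital Autoradiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pipeline for small-scale absorbed-dose estimation in thin
    sequential tissue sections imaged with a single-particle digital
    autoradiography camera. Converts raw frames or listmode event tables
    into decay-corrected activity images, registers consecutive 12-um
    cryosections into a 3D activity stack, generates an At-211-chain
    alpha-particle energy-deposition kernel by continuous-slowing-down
    Monte Carlo transport in water, convolves kernel and stack (FFT) into
    dose-rate maps, partitions tissue by dose-rate non-uniformity,
    fits hot/cold dose-rate kinetics with a double-exponential model and
    integrates absorbed dose, co-registers dose-rate maps with H&E
    histology, and implements two limited-slice approximation methods
    (slice contribution and cloning). Includes a synthetic lymph-node
    phantom generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite,
    minpack.lm,
    tibble,
    ggplot2,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    dplyr
Config/testthat/edition: 3
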