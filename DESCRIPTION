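Package: glossim
Title: Unsupervised Learning of Gloss Perception in a Simulated World
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A self-contained pipeline for studying how gloss perception can
    emerge from unsupervised learning. Renders a controlled world of bumpy
    Lambertian-plus-specular surfaces under fixed light fields, trains a
    PixelVAE-style generative model (convolutional encoder with a compact
    latent code and an autoregressive pixel stream with a discretized
    logistic mixture likelihood) on the renderings, derives continuous gloss
    predictions by linear readout from the latent code, and runs
    representational similarity, simulated-psychophysics, and specular
    highlight-cue analyses, with synthetic observers standing in for human
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    e1071,
    EBImage,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    knitr
Config/testthat/edition: 3
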