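Package: embryostage
Title: Developmental Staging of Zebrafish Embryos from Brightfield Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates the developmental stage (hours post fertilisation) of
    zebrafish embryos from single brightfield images with a compact
    convolutional regression network, and quantifies developmental delay
    between embryo populations incubated at different temperatures. Includes
    the Kimmel temperature-scaling model of developmental rate,
    through-the-origin line fits with bootstrap slope bands for population
    discrimination, partial-freeze transfer learning, DeconvNet-style
    saliency maps, and a synthetic multi-well plate image simulator so the
    whole pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    png,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
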