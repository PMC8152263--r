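Package: oildroprt
Title: Radiative Transfer Simulation of Dispersed Oil in Ocean Color
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates how dispersed oil droplets alter remote sensing
    reflectance of the ocean across trophic water types. Combines a
    chlorophyll-parameterized Case-1 bio-optical model of seawater, a
    Lorenz-Mie engine for the inherent optical properties of polydisperse
    oil droplets, a Monte Carlo solver for radiative transfer under a
    wind-roughened (Cox-Munk) sea surface, and ocean-color analytics
    (band ratios, band differences, color index). Ships synthetic oil
    templates (biodiesel-, lubricant- and crude-like) so the full
    pipeline runs without proprietary measurement data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
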