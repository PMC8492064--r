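Package: axisim
Title: Agent-Based Simulation of Posterior Axis Elongation Driven by
    Stochastic Sox2/Bra Fate Switching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An off-lattice agent-based model of vertebrate posterior body
    elongation in which each progenitor of the progenitor zone (PZ) carries a
    stochastic Sox2-to-Bra ratio that controls its fate (neural tube vs
    presomitic mesoderm), its motility, and its adhesive interactions.
    Includes the trajectory statistics used to characterise cell movements
    (tissue-motion correction, motility and velocity-weighted angle
    distributions, time-averaged mean squared displacement), tissue-scale
    readouts (elongation rate, resident-progenitor displacement, shape
    conservation, doubling-time estimation), per-nucleus Sox2/Bra expression
    quantification (DAPI normalisation, ratio statistics, path profiles,
    digital transverse sections), and synthetic-data generators so every
    analysis stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
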