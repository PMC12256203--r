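Package: nichescape
Title: Eco-Evolutionary Simulation of Niche and Dispersal Evolution on
    Fractal Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Spatially explicit individual-based simulation of annual,
    asexual organisms living on toroidal fractal landscapes. Two patch
    attributes (a temporally fluctuating "temperature" and a static
    "habitat" axis) are generated by periodic spectral synthesis with a
    tunable Hurst index; organisms carry heritable niche optima,
    tolerances, a dispersal probability and a dispersal-mode preference.
    Reproduction follows a Gaussian niche with a tolerance/fecundity
    trade-off, density regulation is Beverton-Holt, and all trait
    evolution proceeds by differential survival of immigrant-founded
    clonal lineages. Includes a fast compiled simulation engine, a
    census analysis pipeline (establishment filtering, individual
    sampling, trait correlations, local-adaptation summaries) and a
    command-line interface for reproducible scenario grids.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
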