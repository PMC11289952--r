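Package: rnlscape
Title: Predator-Vision Analysis of Visual Background Habitats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatiochromatic appearance of natural background
    habitats through the eyes of a modeled predator. Implements
    receptor-noise-limited (RNL) color and luminance distances, spatial-acuity
    viewing-distance modeling, RNL ranked filtering and perceptual clustering,
    the color-adjacency / visual-contrast / boundary-strength / local-edge
    pattern statistic families, chemical-defense scoring, correlation
    filtering with parallel-analysis factor retention and varimax exploratory
    factor analysis, and Bayesian phylogenetic distributional Student-t
    location-scale models comparing defense groups across viewing distances.
    Includes a synthetic scene generator producing cone-catch patch mosaics
    with known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    coda,
    jsonlite,
    rjags,
    stats,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), lme4
Config/testthat/edition: 3
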