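Package: trajexplore
Title: Exploration Measures and Variable Clustering for 2-D Movement
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies spatial exploration behavior from two-dimensional
    movement trajectories recorded in bounded (e.g., virtual) environments.
    Provides quality screening and resampling of raw position logs, a suite
    of fourteen exploration measures (path length, pausing, grid occupancy
    and roaming entropy, minimum convex polygon, divider-method fractal
    dimension, sinuosity, landmark visits and revisits, place revisiting,
    step- and flight-scale turnarounds, area and landmark efficiency),
    hierarchical clustering of variables by squared Pearson correlation with
    principal-component homogeneity, knee-point selection of the number of
    clusters, and a seeded correlated-random-walk simulator for generating
    synthetic cohorts with controllable behavioral traits.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
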