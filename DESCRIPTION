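Package: memphase
Title: Membrane Phase and Trajectory Analysis for Coarse-Grained Thylakoid Lipid Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize coarse-grained (Martini-style) lipid membrane
    configurations and trajectories: membrane thickness statistics and gridded
    thickness maps, mean curvature of the midplane surface, the second-rank
    tail order parameter P2, lateral and three-dimensional diffusion
    coefficients from mean-squared displacements, radial distribution
    functions with hydration-shell peak detection, species-level contact
    matrices with initial-configuration normalization, hemifusion onset
    detection in stacked bilayers, and classification of lamellar versus
    inverted hexagonal (HII) phases. Includes a synthetic-membrane generator
    with known ground truth for every estimator, composition builders for
    thylakoid lipid mixtures at prescribed MGDG content and hydration, GRO
    configuration input/output, pairwise statistical comparison with
    Bonferroni correction, and a configuration-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
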