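Package: moveson
Title: Movement-Quality Features and Interactive Sonification of 2D Motion Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bodily movement recorded as 2D marker
    trajectories and for rendering the movement as sound. Computes the
    kinematic movement-quality indices used in expressive-gesture analysis
    (Energy Index, curvature-velocity Smoothness Index, Directness Index),
    applies motion-capture quality control (trimming, marker-crossover and
    occlusion screening, unit-range normalisation), renders three
    filtered-noise sonification models with velocity-driven mappings and
    8-channel ring spatialization, simulates trajectories and hierarchical
    cohorts with known ground truth, and fits random-intercept linear
    mixed models with likelihood-ratio tests, Tukey-family contrasts and
    marginal/conditional pseudo-R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    multcomp,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
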