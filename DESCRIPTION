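Package: ramforage
Title: Radial-Arm-Maze Analysis of Bumblebee Spatial Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing open-field radial-arm-maze (RAM) foraging
    assays in bees. Provides the maze geometry and visit-sequence records,
    the standard RAM performance statistics (total revisits, correct choices
    before the first revisit, correct choices in the first eight visits,
    time per visit), Monte Carlo null models for chance and stereotyped
    movement built on empirical flower-to-flower transition matrices, an
    agent-based generator of complete synthetic dose-response experiments,
    and the inference stage: all-subsets AIC selection with Akaike weights
    and model averaging over negative-binomial and binomial GLMMs, linear
    mixed models on log time per visit, and Cox proportional-hazards
    survival analysis of the choice at first revisit, including
    Kaplan-Meier curves and a body-size split re-analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmmTMB,
    survival,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
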