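Package: canopyphy
Title: Individual Species-Area and Phylogenetic-Area Relationships for
    Mapped Forest Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spatially explicit neighborhood diversity analysis for fully
    mapped forest census plots. Computes individual species-area
    relationships (ISAR) and classifies each species at each neighborhood
    scale as a diversity accumulator, repeller, or neutral species under a
    heterogeneous Poisson null model with an Epanechnikov kernel intensity
    estimate. Extends the framework to individual phylogenetic-area
    relationships (IPAR) via standardized effect sizes of Faith's
    phylogenetic diversity under tip-label randomization, and tests for
    phylogenetic signal in accumulator/repeller status with NRI/NTI
    dispersion metrics, a Sankoff parsimony permutation test, and the
    Fritz-Purvis D statistic. Includes synthetic generators for mapped
    multispecies point patterns and time-calibrated phylogenies with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    picante,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
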