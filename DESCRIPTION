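Package: filotrack
Title: Reconstruction, Tracking and Quantification of Filopodia in 4D
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated reconstruction and tracking of filopodia in
    time-lapse confocal z-stacks of developing muscle tips. Per-frame
    detection combines superpixel foreground extraction, Hessian-based
    vesselness filtering, 3D topology-preserving skeletonization and
    branch decomposition into line segments; segments are curated via
    scriptable edit commands, linked across frames by a greedy score on
    path-length and direction similarity, and quantified as per-movie
    filopodium counts, maximum-length distributions, exponential-rate
    diagnostics and rank-based group comparisons. Includes a ground-truthed
    synthetic movie generator for validating every stage without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
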