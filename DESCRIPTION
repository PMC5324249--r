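Package: vesselgauge
Title: Continuous Morphometry of Tubular Vascular Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Continuous measurement of vessel geometry from triangulated
    lumen surfaces: interior centerline extraction by distance-weighted
    shortest paths, cross-sectional maximum-diameter and area profiles on
    planes normal to the centerline, tortuosity and arch curvature,
    per-vertex Euclidean distance maps, rigid landmark plus iterative
    closest point registration with signed visit-to-visit surface change
    maps, and the method-agreement statistics (Bland-Altman, Passing-Bablok,
    variance-ratio concordance) used to compare continuous against manual
    measurements.  Includes threshold segmentation of voxel volumes with
    marching-cubes surface extraction, and a parametric aorta-like phantom
    generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    RANN,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
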