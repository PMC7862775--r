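Package: histomorph
Title: High-Content Morphometry of DAB-Stained Brain Tissue Tiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-automated histomorphometry pipeline for brightfield
    immunohistochemistry of brain sections after ischemic stroke. Whole-slide
    scans tiled into grids of RGB images are segmented by colour deconvolution
    of the DAB chromogen, each positive area is described by sixteen shape
    descriptors plus three tile-level occupancy measures (nineteen parameters
    in total), and region-stratified group statistics, PCA morphological
    fingerprints, cross-stain correlation heatmaps, edema-corrected lesion
    volumetrics, and a synthetic-slide generator with planted morphological
    shifts are provided for end-to-end, reproducible analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    png,
    tiff,
    igraph,
    EBImage,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
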