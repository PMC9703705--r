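Package: panicle3d
Title: Digital Traits and Gas-Exchange Normalization for 3D Rice Panicle
    Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-destructive panicle phenotyping from colored 3D point
    clouds. Reads PLY clouds, removes image backgrounds by HSV
    thresholding, segments the panicle by the Visible Atmospherically
    Resistant Index (VARI) combined with voxel-grid connected-component
    labeling, and extracts whole-panicle digital traits: projected
    panicle area from a 36-angle rotational projection sweep around the
    principal axis, voxel count, and green/red color-intensity
    proportions. Partitions the panicle into equal sections along its
    principal axis for spatial trait profiles, and normalizes panicle
    gas-exchange fluxes (carbon assimilation, apparent transpiration)
    by projected area for source-sink comparisons, including water use
    efficiency, percent change, percent fertility and pairwise Pearson
    correlation panels. A synthetic-data module generates branched
    panicle clouds with known ground truth and analytic primitives for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
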