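Package: pixelplex
Title: Pixel-Based Quantification of Multiplex Immunofluorescence and
    Immunohistochemistry Tissue Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pixel-based analysis of sequentially stained tissue
    sections imaged as multiplex immunofluorescence (mIF) and multiplex
    immunohistochemistry (mIHC) tiles. Grayscale marker channels are
    thresholded into binary masks, small pixel groups are filtered out, and
    overlapping myeloid/macrophage marker masks (CD68, CD163, CD206, CD11b,
    CD11c) are decomposed into exclusive single, double, triple and
    higher-order pixel co-expression classes. Nuclei are segmented from the
    DAPI or hematoxylin counterstain and phenotyped by marker density in a
    perinuclear doughnut. An affine co-registration between the chromogenic
    and fluorescent renditions of a tile, estimated from the nuclear
    counterstains, transfers tumor and T-cell masks across geometries and
    pixel sizes, after which marker densities inside and outside the tumor,
    tumor to stroma ratios, and Euclidean-distance-transform proximities
    between tumor-border nuclei and marker pixels are computed. A seeded
    synthetic-tissue simulator generates fluorescent and chromogenic tiles
    with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    ggplot2,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
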