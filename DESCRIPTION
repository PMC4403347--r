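Package: plategrowth
Title: Quantitative Analysis of Growth-Plate Cartilage Elongation from 4D Cell Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting how proliferative-zone chondrocytes elongate
    embryonic growth-plate cartilage, from 4D (x, y, z, t) cell-tracking tables
    and voxel image stacks. Provides trajectory decomposition along the
    proximo-distal axis and linear displacement-versus-initial-position fits,
    cell-cell distance distributions over time, a fixed three-nearest-neighbour
    polygon test for convergent extension, division-orientation and daughter-cell
    rearrangement statistics, multi-threshold voxel decomposition of cell versus
    extracellular-matrix volume, and a parameter-free additive anisotropic
    growth model that predicts cell trajectories from measured cell- and
    ECM-growth rates. A seeded synthetic growing-tissue generator (tracks and
    rendered image stacks with known ground truth) supports validation of every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    withr,
    igraph,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
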