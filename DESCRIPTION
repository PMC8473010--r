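Package: forcemapr
Title: Breakthrough Detection and Phase Mapping for AFM Force-Volume Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated analysis of atomic force microscopy (AFM) force-volume
    experiments on supported lipid bilayers. Detects membrane breakthrough
    (piercing) events in force-distance approach curves by applying local-maximum
    peak detection to the curve at several coordinate rotations, extracts
    breakthrough force and bilayer thickness from paired opposite-curvature
    kinks, reconstructs spatial force and thickness maps on the acquisition
    grid, clusters grid points into liquid-ordered (Lo) and liquid-disordered
    (Ld) phases with k-means, and measures lipid-domain morphology (area,
    perimeter, circularity, height mismatch) from height images. Includes
    synthetic-data generators for force curves, force-map grids and domain
    images with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    tiff
Config/testthat/edition: 3
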