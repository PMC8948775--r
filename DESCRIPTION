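Package: spheromorph
Title: Multiparametric Morphometry of Tumor Spheroid Micrographs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Batch analysis of single-spheroid grayscale micrographs from
    3D-culture invasion and drug-response assays. Segments the spheroid from
    the background, quantifies shape (area, perimeter, circularity, specific
    surface), boundary protrusions, skeleton endpoints, gray-level
    co-occurrence texture entropy, and a radial density profile that splits
    the spheroid into a dense core and an invasive edge. Per-well timecourses
    are summarized by day-0 normalization, a spheroid-disruption statistic
    combining area, core-percentage and entropy changes, and an optional
    correlation of morphology with viability readings. Includes a phantom
    generator with known ground truth for validation and a command-line
    driver for folder-per-condition datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
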