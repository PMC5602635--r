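Package: thrombovol
Title: Thrombus Volumetry from Confocal Z-Stacks and Microfluidic Impedance Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies platelet-aggregate (thrombus) volume formed under flow in a
    microfluidic chamber by two independent routes and fuses them. The optical route
    selects an intensity threshold automatically from the elbow of the volume-versus-
    threshold curve of a confocal z-stack and integrates thresholded areas into a
    volume with a propagated uncertainty. The electrical route solves a finite-volume
    conduction model of the channel with coplanar u-shaped electrodes and inverts a
    measured impedance magnitude into a height scale factor, a volume estimate and a
    watertight 3-D reconstruction. Impedance traces recorded during perfusion are
    classified into four adhesion/aggregation behaviors and scanned for abrupt
    detachment events. A synthetic-fixture generator produces paired z-stacks,
    projection images and impedance traces with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
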