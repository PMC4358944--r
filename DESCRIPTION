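Package: vitroquant
Title: Quantitative Image Analysis of Airway Vitronectin Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the quantitative image-analysis chain used to measure
    vitronectin expression in airway tissue: mean+2SD background thresholding
    and voxel/intensity summation on dual-channel confocal z-stacks, Pearson
    and Manders colocalization coefficients with joint-intensity scatter maps,
    81-point-grid (Cavalieri) stereological volume fractions and area
    fractions on labelled tissue sections, intensity-per-area quantification,
    western-blot lane densitometry with loading-control normalization, and a
    nonparametric cohort-statistics layer (D'Agostino-Pearson normality,
    Kruskal-Wallis with Dunn's post test, pooled t-test). A synthetic-data
    generator produces dual-channel stacks, section label maps, cohorts and
    gel lanes with known ground truth so every stage is testable without
    tissue images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
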