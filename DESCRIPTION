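Package: ReefChange
Title: Depth-Invariant Benthic Indices, Generalized Coral Classification
    and Two-Epoch Change Detection for Shallow-Water Multispectral Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying coral-cover change from Landsat-like
    multispectral radiance scenes of shallow reef waters.  Implements
    Lyzenga water-column correction (dark-pixel subtraction, band-pair
    attenuation-coefficient ratio estimation, per-pixel depth-invariant
    indices), a cross-site-generalizable coral/non-coral classifier built
    on a radial-basis support vector machine with grid-search
    cross-validation, remote-sensing accuracy metrics (precision, recall,
    specificity, accuracy, F-measure, Cohen's kappa, ROC/AUC), and
    per-pixel post-classification change detection with pixel-to-area
    accounting.  A seeded radiative forward simulator generates two-epoch
    synthetic reef scenes with ground-truth percent-cover tables so every
    stage is testable without satellite downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
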