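Package: aquacol
Title: Aqueous Column Width and Flow Analysis for Hemoglobin Video Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for hemoglobin video imaging of episcleral
    veins: synthetic vein video generation with known ground truth,
    lossless AVI input/output, frame-rate handling, blink detection and
    post-blink segment selection, translation-only video stabilization by
    phase correlation, aqueous-column width measurement from
    cross-sectional intensity profiles (distance between the two flanking
    blood-lane minima, with subpixel refinement), per-pixel temporal
    autocorrelation flow metrics, and the statistical layer of a
    two-sequence 2x2 crossover trial (exact rank tests and a
    random-intercept linear mixed model fitted by restricted maximum
    likelihood).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
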