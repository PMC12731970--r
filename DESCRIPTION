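Package: mirrorsim
Title: Headless Simulation and Objective Scoring of Dental Mirror-Technique Skills
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A headless geometric simulator and scoring pipeline for
    virtual-reality evaluation of dental mirror-technique (indirect vision)
    skills. Implements planar-mirror virtual-image optics with a symmetric
    mirror-image camera, perspective projection of the circular mirror head
    and caries lesion to image-space ellipses, rasterisation of labelled
    screenshots, moment-based ellipse re-measurement with pixel-to-millimetre
    calibration, the four mirror-technique skill metrics (distance between
    centres, relative lesion area ratio, lesion ellipticity, manipulation
    time), task validity criteria, a calibrated synthetic operator-cohort
    generator, and the nonparametric group-comparison battery
    (Kolmogorov-Smirnov normality screen, Friedman test, Bonferroni-adjusted
    pairwise comparisons, Cohen's d).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse
Config/testthat/edition: 3
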