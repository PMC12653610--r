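Package: rubbergrade
Title: Automated Colorimetric Grading of Natural Rubber Specimens
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end colorimetric image analysis for objective quality
    grading of natural rubber (white crepe, STR5, STR5L, RSS3, RSS5).
    Provides radiometric flat-field correction with dark and white
    reference frames, Gaussian denoising, image quality gates (SNR,
    illumination uniformity, saturation, focus), Otsu threshold
    segmentation with morphological refinement and geometric ROI
    validation, device-independent color math (sRGB linearization,
    RGB to CIE XYZ tristimulus, CIELAB, ASTM E313-style yellowness
    index, CIE76 colour difference), hierarchical threshold
    classification with calibration from labelled training data, and a
    statistical validation layer (one-way ANOVA, Tukey HSD,
    repeatability and reproducibility, Monte-Carlo uncertainty
    propagation, colour-chart calibration reports). A seeded synthetic
    scene generator emulates the imaging rig so the full pipeline is
    testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
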