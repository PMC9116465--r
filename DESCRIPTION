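Package: ceiqa
Title: No-Reference Quality Assessment for Circular-FOV Confocal Endoscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Blind (no-reference) image quality assessment for confocal
    laser endoscopy images with a circular field of view. Perceptual
    features are built from Weber's-law differential excitation, a
    rotation-invariant uniform local binary pattern map, their joint
    histogram, and a Weber-thresholded local ternary pattern with an
    adaptive relative-contrast threshold, extracted over a three-scale
    pyramid into a 444-dimensional descriptor. A support-vector
    regression with radial-basis kernel maps the descriptor to a quality
    score. The package also ships the standard evaluation protocol
    (SROCC/PLCC/RMSE with a five-parameter logistic remapping, repeated
    random train/test splits, corrected resampled paired t-tests) and a
    synthetic generator of circular-field-of-view phantoms with graded
    blur, noise, and contrast distortions and pseudo mean-opinion-score
    labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    minpack.lm,
    png,
    stats,
    tools,
    utils
Suggests:
    jpeg,
    jsonlite,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
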