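Package: kiwifuse
Title: Computer Vision and Electronic Nose Data Fusion for Kiwifruit
    Quality and Origin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for predicting physicochemical
    quality attributes and classifying the geographical growing region of
    red-fleshed kiwifruit from fused computer-vision and electronic-nose
    measurements. Includes a synthetic-data generator for fruit images
    (whole and equatorial middle-cut), 13-channel metal-oxide gas-sensor
    response curves, and per-fruit physicochemical records; segmentation of
    cross-section tissues by Otsu thresholding of hue and excess-green (ExG)
    channels; extraction of a 46-element visual feature vector and 13
    maximum-sensor-response features; and feature-level fusion with PCA
    reduction and grid-searched support vector classification and regression
    under ten-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
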