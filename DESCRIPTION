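Package: scenegaze
Title: Eye-Movement Screening, Gaze Metrics and Image Statistics for
    Aerial Scene Viewing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing eye-tracking experiments in which observers
    categorize aerial (overhead) scene images.  Implements the complete event
    screening procedure for trials, fixations and saccades; fixation density
    map entropy, gaze transition entropy over an area-of-interest grid,
    center-bias scoring with bootstrap standard errors, and observer-to-image
    -to-category aggregation; low-, mid- and object-level image statistics
    (Gabor filter-bank energies, gray-level co-occurrence homogeneity,
    CIELAB luminance, critical-object saliency from polygon annotations);
    embedding-based perceptual similarity and PCA-space norms; luminance-
    controlled bidirectional stepwise AIC regression with collinearity and
    repeated-measures power utilities; rotation-invariance testing of image
    statistics at right angles; and a fully seeded synthetic-data generator
    that emulates the experimental design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
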