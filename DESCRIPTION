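Package: metricCP
Title: Metric-Guided Conformal Prediction Bounds for Probabilistic Image
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distribution-free prediction intervals for scalar clinical
    metrics derived from ensembles of stochastically reconstructed images
    (for example sparse-view CT reconstructions). Calibrates split
    conformal quantile adjustments on a calibration set of metric
    ensembles with known ground truth, constructs statistically valid
    prediction intervals for new subjects, and maps the interval back to
    nearest-neighbour reconstructions, inliers and outliers. Includes a
    fat-volume metric based on Hounsfield-unit windowing, pixel-wise
    baseline bounds, a repeated random-split evaluation harness, a
    synthetic ensemble and CT-phantom generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    optparse,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
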