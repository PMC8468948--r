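Package: hsibruise
Title: Hyperspectral Detection and Aging of Invisible Mechanical Damage in Persimmon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for detecting mechanically induced, visually disguised
    bruises in persimmon fruit from visible/near-infrared hyperspectral
    reflectance cubes (60 bands, 450-1040 nm) and for classifying how many
    days ago the damage occurred. Provides white/dark reflectance
    calibration, spectral preprocessing (Savitzky-Golay smoothing and
    derivatives, standard normal variate, mean centring), pixel-spectrum
    principal component analysis, PCA-based fruit and bruise segmentation
    with Otsu thresholding and morphological/shape filtering, a NIPALS
    PLS-DA damage-age classifier with cross-validated latent-variable
    selection, and a synthetic hypercube generator with ground-truth masks
    so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
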