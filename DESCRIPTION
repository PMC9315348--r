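Package: decaymap
Title: Hyperspectral NIR Imaging Analysis of Progressive Fungal Wood Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chemometric analysis of short-wavelength-infrared
    hyperspectral images of brown-rot decayed wood. Implements cube
    preprocessing (spatial median filtering, dark/white reflectance
    calibration, standard normal variate transformation, absorbance
    conversion, PCA-based background and saturation masking, region-of-
    interest extraction and band trimming), ANOVA-simultaneous component
    analysis (ASCA) of balanced factorial designs with sum-of-squares
    partitioning, effect combination, per-effect singular value
    decomposition, residual projection and permutation significance
    testing, mosaic PCA of unfolded pixel spectra with extreme-pixel
    removal and score-map refolding, and k-means segmentation of PCA
    score space into decay classes. A synthetic phantom generator
    produces two-tissue wood-decay images and stacked-experiment average
    spectra with exact ground truth, so the whole pipeline is testable
    end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
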