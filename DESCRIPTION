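Package: hsibean
Title: Pixel-Wise and Object-Average Classification of Seed Varieties from
    Near-Infrared Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end chemometric pipeline for variety identification of
    granular samples (e.g. coffee beans) imaged with a line-scan NIR
    hyperspectral camera. Reads and writes ENVI-style reflectance cubes,
    performs white/dark reflectance correction, single-band Otsu masking with
    8-connected bean instance labelling, and extracts pixel-wise and
    sample-average spectra. Implements the four preprocessing families
    compared in this setting (spectral moving average, spatial median filter,
    wavelet soft-threshold denoising, empirical mode decomposition denoising),
    second-derivative optimal-wavelength selection, one-vs-one RBF support
    vector machine calibration with grid-searched hyperparameters, the
    pixel-wise versus sample-average cross-prediction experiments, and
    per-pixel prediction maps. A synthetic-scene generator with elliptical
    beans, a multiplicative center-to-edge path-length gain and additive
    pixel noise makes every stage testable without proprietary image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    kernlab,
    signal,
    png,
    EBImage,
    Rcpp,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
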