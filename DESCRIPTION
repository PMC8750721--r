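Package: calyxscan
Title: Pixel-Level NIR Hyperspectral Detection of Codling Moth Infestation in Apples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for detecting codling moth (Cydia pomonella)
    infestation in apples from near-infrared (900-1700 nm) hyperspectral
    reflectance images at the pixel level. Provides ENVI-format hypercube I/O,
    white/dark reference reflectance calibration, automatic calyx-centered
    region-of-interest acquisition (Otsu thresholding, binary erosion,
    centroid localization, circular masking), a chemometric preprocessing
    chain (wavelength trimming, maximum normalization, Savitzky-Golay
    smoothing, mean centering), Kennard-Stone train/validation splitting,
    PCA feature extraction with a bank of classifiers (LDA, kNN, SVM, random
    forest, gradient tree boosting, PLS-DA, AdaBoost), sequential forward
    wavelength selection for multispectral model design, and a synthetic
    apple-scene generator for end-to-end validation when real fruit data are
    unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    class,
    e1071,
    randomForest,
    xgboost,
    rpart,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
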