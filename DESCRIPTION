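Package: qusresponse
Title: Quantitative Ultrasound Pipeline for Pre-Treatment Chemotherapy Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates radiofrequency (RF) ultrasound cohorts, estimates the five
    classical quantitative-ultrasound spectral parameters (midband fit, spectral
    slope, spectral intercept, average scatterer diameter and average acoustic
    concentration) by reference-phantom normalization and spherical Gaussian
    form-factor fitting, assembles sliding-window parametric maps, extracts
    frozen convolutional backbone features from the map images, and classifies
    tumors into chemotherapy responders and nonresponders with ANOVA feature
    selection, SMOTE class balancing and a linear support vector machine.
    Includes leakage-guarded train/test handling, stratified splitting,
    cross-validation and confusion-matrix based reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    signal,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
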