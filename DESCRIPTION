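Package: noduleCAD
Title: Lung Nodule Computer-Aided Diagnosis on CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale computer-aided diagnosis (CAD) pipeline for
    pulmonary nodules on grayscale CT slices. Implements wavelet-subband
    Bayesian-threshold denoising with BM3D-style collaborative filtering,
    histogram-entropy redundant-frame elimination, Z-score intensity
    normalization, gray-level co-occurrence (GLCM) texture plus shape,
    intensity and semantic feature extraction from nodule masks, a compact
    convolutional neural network classifier trained with Adam whose
    hyperparameters are tuned by particle swarm optimization, and
    confusion-matrix evaluation metrics. A synthetic phantom generator
    produces reproducible CT-like nodule images, masks and class-conditional
    sensor records so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, grDevices, tools, png, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
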