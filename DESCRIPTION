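Package: strokehar
Title: Data Augmentation and Classifier Training for Stroke-Patient
    Activity Recognition from Wearable IMU Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how time-series data augmentation
    (rotation, permutation, time-warping) affects deep classification of
    activities of daily living recorded by body-worn inertial measurement
    units, with a focus on hemiparetic stroke patients whose movement data
    are sparse and heterogeneous.  Provides a calibrated synthetic cohort
    generator emulating non-disabled and stroke movement statistics
    (amplitude attenuation, inter-subject signal coherence, severity
    coupling), the full preprocessing chain (linear resampling, channel
    centering, modality scaling, trailing moving average, sliding
    windows), seed-controlled augmentation transforms, one-dimensional
    convolutional and InceptionTime classifiers trained with AdamW, and
    leave-one-subject-out, train-on-synthetic-test-on-real, transfer
    learning and subject-subset evaluation protocols with macro-F1
    scoring and severity correlation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    data.table,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
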