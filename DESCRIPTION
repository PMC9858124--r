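Package: tremorclass
Title: Pathological Tremor Detection from Kinematic and Electromyographic
    Signals
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for binary detection of pathological
    (essential) tremor from wearable-sensor signals. Simulates virtual
    cohorts of tremor patients and healthy controls (hand/forearm IMU
    quaternion streams and bipolar surface EMG from wrist flexor and
    extensor muscles), converts quaternions to the wrist flexion-extension
    angle, extracts tremor-band EMG envelopes, auto-labels one-second
    windows by a tremor-band (4-10 Hz) power-spectral-density peak
    threshold, and trains and evaluates four classifier families
    (distance-weighted k-nearest neighbours, RBF support vector machines,
    random forests, and a two-layer LSTM network trained by
    backpropagation through time) on three input modalities: wrist angle,
    EMG envelope, and raw EMG. Reports precision, recall, specificity,
    accuracy and F1 per model and modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    ranger,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
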