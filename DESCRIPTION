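Package: harspect
Title: Spectral Feature Extraction, Feature-Space Augmentation and Stacked
    LSTM Classification for Wearable IMU Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for recognising human activities (standing,
    sitting, walking) from 6-axis inertial measurement unit (IMU) streams.
    Implements spectrogram-based feature extraction that abstracts each
    analysis window into its smallest and largest pooled spectral densities,
    a feature-space data-augmentation ensemble built from grouped local
    averaging and per-class shuffling, a stacked long short-term memory
    (LSTM) classifier with peephole-style gates trained by backpropagation
    through time with Adam, and a confusion-matrix evaluation harness with
    accuracy, precision, recall and F1 reporting. A seeded synthetic IMU
    generator makes the whole pipeline testable without sensor hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    caret,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
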