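Package: eegmtc
Title: Subject-Independent Mental-Task Classification from EEG Band-Power Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for subject-independent classification of
    imagined mental tasks (left-hand movement, right-hand movement, word
    generation) from multichannel EEG. Raw recordings are spatially sharpened
    with a surface (small) Laplacian filter, converted to 96-dimensional
    power-spectral-density band features (8 centro-parietal channels x 12
    bins, 8-30 Hz at 2 Hz resolution), task-wise averaged within and across
    subjects to suppress inter-subject variability, reduced with principal
    component analysis, and classified with a feed-forward neural network
    trained by minibatch Adam or stochastic gradient descent. Evaluation uses
    leave-one-subject-out cross-validation with confusion matrices and
    micro/macro/weighted precision, recall and F1. A seeded synthetic
    multi-subject EEG generator with controllable subject shift makes every
    stage testable without any external dataset; readers and writers for the
    whitespace-separated ASCII feature-file dialect of the BCI competition
    III dataset V are included.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
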