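Package: erdbench
Title: Benchmarking Classifiers for EEG Movement-Intention Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects the intention to perform an arm movement from multichannel
    EEG before the movement starts, using the event-related desynchronization
    (ERD) of the mu and beta rhythms. Implements the full detection chain:
    an idealized 10/10 electrode montage with an inverse-distance surface
    Laplacian spatial reference, 50-Hz notch and 8th-order Butterworth
    band-pass filtering, FFT band-power features (three band sums per
    electrode), and a seven-classifier benchmark (least-squares, quadratic
    programming and SMO support vector machines, k-nearest neighbours with
    k = 10, 20, 30, and Gaussian naive Bayes) evaluated by leave-one-run-out
    cross-validation with true/false positive rates, their ratio (GAP) and
    ANOVA comparisons. A synthetic ERD session generator reproduces the
    cued reaching protocol (3 s rest cross, 5 s movement point, cursor trace
    at 16 Hz) so that every stage is testable without subject recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    kernlab,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
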