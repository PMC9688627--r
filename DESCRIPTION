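Package: restingEEG
Title: Nonlinear Complexity Features and Sequence Classifiers for
    Resting-State EEG Depression Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A data-driven pipeline for classifying depressive versus
    control subjects from a few resting-state EEG electrodes. Provides a
    synthetic eyes-closed EEG cohort generator with class-dependent 1/f
    spectral complexity, EDF(+) input/output, the standard preprocessing
    chain (band-pass, 50 Hz notch, 90 Hz low-pass, average reference,
    cropping, 200 Hz resampling, L2-normalised 1 s windows), from-scratch
    implementations of six nonlinear complexity features (permutation,
    sample, spectral and singular-value-decomposition entropies, detrended
    fluctuation analysis, Higuchi fractal dimension), Desikan-region to
    10-20 electrode lookups, data-driven selection of time-window span,
    key electrode group and feature combination via cross-validated
    baselines and paired t-tests, mutual-information feature ranking, and
    a classifier suite (logistic regression, RBF support vector machine,
    multilayer perceptron, 1-D convolutional, stacked LSTM and Conv1D+GRU
    networks) with evaluation utilities (confusion metrics, ROC/AUC,
    summary-statistic t-tests, external validation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
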