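Package: eegoutcome
Title: EEG Spectral Topography and Coherence Connectivity for Tinnitus
    Treatment-Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts tinnitus treatment response (responder versus
    non-responder, labelled from the change in the Tinnitus Functional
    Index) from 64-channel resting EEG.  Provides rate conversion and
    one-second epoching, per-epoch DFT band-amplitude extraction over the
    theta/alpha/beta bands, Delaunay-interpolated 32x32 scalp topographies,
    Welch magnitude-squared coherence connectivity matrices with
    thresholded graph export, channel-importance ranking including the
    greatest-change channel-selection statistic, compact convolutional and
    multilayer-perceptron classifiers with stratified splitting and k-fold
    evaluation, and a synthetic two-group EEG cohort generator with planted
    spectral, connectivity and pre-to-post amplitude structure for
    end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
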