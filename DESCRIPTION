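Package: postrosc
Title: Rearrest Prediction from Post-ROSC ECG Segments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to predict rearrest after return of spontaneous
    circulation (ROSC) in out-of-hospital cardiac arrest from short
    single-channel ECG segments. Implements the full pipeline: band-pass
    preprocessing, Hamilton-Tompkins QRS detection with a variance-based
    correction, a secondary curve-length detector and a beat-agreement
    signal quality index, 17 heart rate variability features (time domain,
    Lomb-Scargle spectral, Poincare and sample entropy) plus 4 ECG waveform
    features (spectral centroid, amplitude, relative QRS power, QRS width
    variability), a class-balanced random forest with out-of-bag
    permutation importance, and repeated stratified patient-wise
    cross-validation with ROC/PR analysis. A synthetic ECG cohort
    simulator with ground-truth beat annotations supports development and
    validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
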