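Package: ramanpeaks
Title: Peak-Fitting Dimensional Reduction and SVM Classification for
    Raman Micro-Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for tissue classification from Raman micro-spectra.
    Implements spectral preprocessing (accumulation summing, cosmic-ray
    despiking, rolling-ball baseline subtraction, standard normal variate
    normalization, per-core averaging), a Gaussian peak-fitting dimensional
    reduction step that turns consensus Raman peaks into fitted height and
    width features, dual-track L1-SVM feature ranking with wavenumber
    neighborhood redundancy removal, RBF-kernel SVM classification under a
    repeated, patient-grouped, cross-validated randomized grid search, and
    ROC-based evaluation including the paired DeLong test for comparing
    correlated ROC curves. A built-in synthetic Raman cohort simulator with
    known ground truth makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
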