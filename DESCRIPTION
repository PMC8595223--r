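Package: hemoscreen
Title: In-Silico Screening of Arterial Disease from Pulse-Wave Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates virtual patient cohorts with a one-dimensional
    pulse-wave propagation model of the systemic arterial network, introduces
    parameterised stenoses and aneurysms (carotid, subclavian,
    iliac-femoral-popliteal, and abdominal aortic lesions), featurises the
    resulting pressure and flow-rate waveforms as truncated Fourier series,
    and trains and evaluates machine-learning classifiers over all
    combinations of bilateral measurement sites. Provides screening metrics
    (F1, sensitivity, specificity), measurement-combination search,
    split-improvement feature importance, low-severity aneurysm analysis,
    and unilateral measurement tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils,
    ranger,
    xgboost,
    e1071,
    glmnet,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
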