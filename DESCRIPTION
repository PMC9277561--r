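Package: eegresponse
Title: Band-Power Biomarkers and Treatment-Response Prediction from
    Pre/Post Resting EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pre- versus post-treatment resting-state
    EEG studies of clinical treatment response. Implements deterministic
    signal conditioning (common-average re-referencing, baseline removal,
    zero-phase Butterworth band-pass filtering, fixed-length segmentation),
    Welch power spectral density estimation with band-power averaging over
    canonical EEG bands, band-power change-rate statistics compared between
    responders and non-responders with normality- and variance-gated test
    selection and false-discovery-rate control, and prediction of responder
    status from pre-treatment band powers with a cross-validated RBF-SVM,
    greedy forward channel selection and permutation-based significance.
    Includes a calibrated synthetic-cohort generator so the full pipeline
    can be exercised and validated without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    parallel,
    signal,
    e1071,
    nortest,
    car,
    jsonlite,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
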