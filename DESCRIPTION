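Package: capmech
Title: Coronary Plaque Cap Mechanics and Vulnerability-Index Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for coronary plaque vulnerability from
    segmented IVUS+OCT cross-section contours: morphological risk factors
    (lumen area, plaque area, plaque burden, fibrous-cap thickness),
    zero-load geometry recovery by axial and circumferential pre-shrink,
    a thin-slice anisotropic modified Mooney-Rivlin finite-element model
    for cap stress and strain, plaque vulnerability index (PVI) scoring
    and threshold calibration, and random-forest prediction of
    baseline-to-follow-up PVI changes with a repeated cross-validated
    sweep over all predictor combinations. Includes a seeded synthetic
    cohort generator so the full pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    pracma,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
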