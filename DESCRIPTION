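Package: pulsewedge
Title: Wrist Photoplethysmography Morphology Analysis for Pulmonary
    Capillary Wedge Pressure Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking wrist photoplethysmography (PPG) waveform
    morphology to pulmonary capillary wedge pressure (PCWP). Implements
    analysis-window selection and zero-phase Butterworth band-pass
    preprocessing, beat segmentation with fiducial-point detection, six
    pulse-wave features (heart rate, heart rate variability, systolic and
    diastolic amplitude, crest time, large artery stiffness index),
    cross-validated single-feature linear regression and linear
    discriminant classification with pooled out-of-fold metrics, and
    Mann-Whitney group comparisons with Bonferroni correction. Includes a
    synthetic PPG cohort generator with known ground-truth morphology,
    rhythm, noise, and PCWP-morphology coupling for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    MASS,
    withr,
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
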