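Package: neurobalance
Title: EEG and fNIRS Biomarkers of Balance Function After Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts movement-related brain biomarkers from combined EEG and
    functional near-infrared spectroscopy (fNIRS) recordings of an ankle
    dorsiflexion task and relates them to clinical balance scores. Implements
    event-related spectral perturbation (ERSP) with subtractive baseline
    normalization and a scalar event-related desynchronization (ERD) index,
    Hilbert-transform phase synchronization between channel pairs, band-pass
    filtered and baseline-corrected hemoglobin (HBO/HBR/HBT) epoch averages
    with peak and area features, and a multiple linear regression of the Berg
    Balance Scale on age, ERD and HBO validated by leave-one-out
    cross-validation. A synthetic-data module simulates EEG oscillations with
    controllable desynchronization depth, phase-coupled channel pairs with
    known synchronization, hemodynamic responses with physiological noise,
    and feature cohorts from a known generating model, so the whole pipeline
    is testable without recording hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
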