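Package: ipceval
Title: Evaluation Toolkit for Internet-Based Pharmaceutical Care in Hypertension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the evaluation machinery used to assess an
    internet-based pharmaceutical-care (IPC) intervention for young and
    middle-aged hypertensive patients: Likert questionnaire scoring with
    reverse-coded items and blood-pressure control classification; a
    NIPALS-PCA reliability screen with a 99% Hotelling T-squared control
    ellipse and per-variable contribution diagnostics; two-class OPLS-DA
    with S-plot coordinates and signed-VIP variable selection; and a
    three-state Markov cohort model (poorly controlled, well controlled,
    dead) with life-year, QALY, cost-effectiveness-ratio and one-way
    sensitivity analyses. A moment-calibrated synthetic-cohort generator
    emulates the study structure so the whole pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
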