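Package: ciedtriage
Title: Flagging 90-Day Cardiac Implantable Electronic Device Infections
    from Electronic Medical Record Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Surveillance toolkit for detecting 90-day infections after
    cardiovascular implantable electronic device (CIED) procedures from
    electronic medical record extracts. Combines structured flags
    (diagnosis codes, antibiotic courses, microbiology cultures, fever,
    mortality) with rule-based keyword mining of clinical note text,
    scores each procedure with a logistic triage model, and queues
    high-probability cases for manual record review at a predicted
    probability threshold. Includes the full validation machinery
    (positive predictive value, sensitivity, specificity with exact
    confidence intervals, ROC/AUC, probability-band tables, Cohen's
    kappa) and a seeded synthetic EMR generator with planted infections
    so every stage is testable without protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
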