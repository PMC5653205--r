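Package: epoctr
Title: Electronic Algorithms for Pediatric Fever Triage and Non-Inferiority Trial Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Executable rule engines for two electronic patient-management
    algorithms for febrile children aged 2-59 months at primary-care level:
    e-POCT, which combines a small set of clinical signs with staged
    point-of-care tests (malaria rapid test, haemoglobin, pulse oximetry,
    glucose, and the host biomarkers C-reactive protein and procalcitonin)
    to triage severe disease and target antibiotic prescription, and the
    IMCI-derived ALMANACH comparator. The package also encodes the
    day-7 clinical-failure and day-30 severe-adverse-event outcome
    definitions used to evaluate such algorithms, the non-inferiority
    trial statistics that analyse them (risk difference and Katz risk
    ratio with confidence intervals, Mantel-Haenszel stratified risk
    ratios, chi-squared tests, number needed to treat, sample-size and
    power calculations, block randomization, intention-to-treat and
    per-protocol population construction, Kaplan-Meier fever-resolution
    curves), and a seeded synthetic-cohort simulator with latent
    etiologies, condition-conditioned biomarkers and
    management-dependent follow-up so the full pipeline runs at desk
    scale without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
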