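Package: vttrial
Title: Simon Two-Stage Design, Exact Post-Design Inference and Venous
    Tumour Thrombus Endpoint Derivation for Single-Arm Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing single-arm phase II trials
    with a Simon two-stage binomial stopping rule, motivated by neoadjuvant
    studies of venous tumour thrombus (VTT) in renal cell carcinoma.
    Provides exhaustive enumeration of minimax and optimal two-stage
    designs with exact operating characteristics; design-adjusted exact
    inference after adaptive stopping (stage-wise p-value function,
    median-unbiased estimate, confidence intervals by test inversion in
    the style of Koyama and Chen, and the UMVUE of the response
    probability); derivation of trial endpoints from longitudinal imaging
    records (Mayo thrombus level classification and improvement calls,
    percent change in thrombus length, RECIST v1.1 target-lesion response,
    change in surgical approach, Cockcroft-Gault creatinine clearance and
    eligibility screening); a seeded synthetic-cohort generator plus a
    deterministic 20-patient reference cohort; and an end-to-end analysis
    pipeline producing a trial report with CONSORT accounting, endpoint
    tables and design-adjusted inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
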