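Package: adpkdprog
Title: Lifetime Disease-Progression Model for Rapidly Progressing ADPKD
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Cohort simulation of lifetime chronic kidney disease (CKD)
    progression in autosomal dominant polycystic kidney disease (ADPKD)
    patients at risk of rapid progression (Mayo imaging subclasses 1C-1E).
    Predicts annual eGFR decline with the Irazabal prediction equation,
    moves a stratified cohort through the six KDIGO health states G1-G5
    (G5 = end-stage renal disease) and death on an annual cycle, applies a
    constant tolvaptan treatment effect with time-varying discontinuation,
    scales period life-table mortality by CKD-state risk ratios, and reports
    time to ESRD, delay of ESRD, life-years by health state, and percentile
    intervals from probabilistic sensitivity analysis. Includes synthetic
    life-table and cohort generators so every analysis runs offline, a
    YAML-configured run pipeline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
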