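Package: pcabsim
Title: Whole-Body PBPK/PD Simulation and Dose Screening for Potassium-Competitive Acid Blockers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-body physiologically based pharmacokinetic (PBPK) model with
    first-order oral absorption and hepatic elimination, coupled to a
    mechanism-based gastric acid-suppression pharmacodynamic model for
    potassium-competitive acid blockers (P-CABs). Provides non-compartmental
    summary metrics, terminal-slope calibration against observed plasma data,
    local sensitivity analysis, clinical-endpoint metrics (pH > 4 holding time
    and onset), and dose-sweep screening across compounds. Also ships compact,
    testable implementations of the parameter-prediction machinery used
    upstream of such models: a message-passing neural network forward pass on
    molecular graphs, an m5p model-tree random forest with variance-minimizing
    splits and linear leaves, k-fold model selection by mean absolute error,
    and the deterministic derived-ADME formulas (fraction unbound from plasma
    protein binding, clearance from volume and half-life, absorption rate from
    Caco-2 permeability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
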