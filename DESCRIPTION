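Package: tewlbalance
Title: Transepidermal Water Loss Estimation and ICU Fluid-Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying 24-hour transcutaneous water loss in
    critically ill patients two ways - direct transepidermal water loss (TEWL)
    measurements extrapolated to body surface area by the Wallace rule of
    nines, and the Cox weight/temperature estimation formula with ventilation
    reduction - and for folding either estimate into 24-hour fluid-balance
    ledgers. Includes an open-chamber evaporimeter model (Fick's-law vapor
    flux from paired humidity/temperature sensors and the standard-deviation
    stabilization stopping rule), a statistical pipeline (normality-gated
    two-group comparisons, paired method comparison, site-wise ANOVA with
    step-down Sidak adjustment, within-patient percent-of-mean normalization
    and regression against systemic vascular resistance), and a synthetic
    ICU-cohort generator that emulates the statistical structure of a
    septic/cardiogenic shock feasibility cohort so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
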