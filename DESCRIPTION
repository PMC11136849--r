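Package: residuval
Title: Matrix-Matched Calibration, Validation, and Monitoring QA/QC for
    Multi-Residue Pesticide Analysis in Soils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification and method-validation toolkit for targeted
    GC-MS/MS multi-residue pesticide analysis of soils with QuEChERS
    extraction. Fits external and internal (isotope-labeled internal
    standard) matrix-matched calibration curves, quantifies matrix effects
    and compares calibration slopes across soil types, computes SANTE-style
    validation statistics (repeatability and reproducibility RSDs, absolute
    and relative recovery, signal-to-noise based limits of quantification,
    Horwitz precision bounds), and applies selectivity, blank-referencing,
    occurrence, and sum-exceedance rules to routine monitoring batches. A
    synthetic peak-area generator with a ground-truth ledger supports
    parameter-recovery testing, and the published per-compound validation
    table ships as a packaged fixture.
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
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
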