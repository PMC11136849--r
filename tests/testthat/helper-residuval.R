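suppressPackageStartupMessages({
  library(dplyr)
  library(tidyr)
})

# Small three-analyte registry: alpha has a structure-identical IL-IS
# (alpha-d5, group 1), beta shares group 1 as a non-si analyte, gamma is
# quantified by the non-si standard gamma-d3 (group 2).
toy_registry <- function() {
  tibble::tibble(
    name = c("alpha", "beta", "gamma", "alpha-d5", "gamma-d3", "TPP"),
    category = c("herbicide", "fungicide", "insecticide_acaricide",
                 "internal_standard", "internal_standard", "syringe_standard"),
    ilis_group = c(1L, 1L, 2L, 1L, 2L, NA_integer_),
    si_ilis = c(TRUE, FALSE, FALSE, NA, NA, NA),
    expected_rt = c(7, 9, 11, 7, 11, 14)
  )
}

# Deterministic, noise-free ground truth: unit recovery, flat response
# factor, a single shared enhancement factor per soil.
noiseless_truth <- function(registry, f = 1, seed = 99, recovery = 1,
                            response_factor = 1000) {
  nm <- registry$name
  base <- c(SR = f, RFNo = f, RFNc = f, XFN = f, DC = f)
  ground_truth(
    registry, seed = seed,
    response_factor = stats::setNames(rep(response_factor, length(nm)), nm),
    extraction_recovery = stats::setNames(rep(recovery, length(nm)), nm),
    matrix_base = base, matrix_spread_sdlog = 0,
    day_effect_sd = 0, injection_cv = 0, ion_ratio_cv = 0
  )
}

toy_design <- function(...) {
  design_spec(matrices = c("solvent", "SR"), validation_matrix = "SR",
              cal_replicates = 1, ...)
}
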