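#' Relative standard deviation
#'
#' `100 * sd(values) / mean(values)` with the sample (n - 1) standard
#' deviation.
#'
#' @param values Numeric vector of at least 2 replicate results.
#' @return RSD in percent.
#' @examples
#' rsd(c(9, 10, 11)) # 10
#' @export
rsd <- function(values) {
  if (length(values) < 2) {
    abort("RSD needs at least 2 replicate values.",
          class = "residuval_insufficient_replicates_error")
  }
  m <- mean(values)
  if (m == 0) {
    abort("RSD is undefined for a zero mean.",
          class = "residuval_undefined_rsd_error")
  }
  100 * sd(values) / m
}

#' Repeatability and reproducibility per compound and level
#'
#' Repeatability (RSDr) is the RSD of the within-one-day replicates;
#' reproducibility (RSDR, within-laboratory) pools the replicates of all
#' days (12 values in the reference quadruplicate-by-3-days design).
#' By default the first complete day defines repeatability; pass
#' `repeatability_day` to designate another.
#'
#' @param concentrations A tibble with columns `compound`, `nominal_conc`
#'   (fortification level), `day`, `replicate`, `conc_ng_g` (e.g. from
#'   [quantify_samples()] restricted to fortified samples).
#' @param repeatability_day Day whose replicates define RSDr; `NULL` picks
#'   the first day with >= 2 replicates at every (compound, level).
#' @return A tibble `compound`, `nominal_conc`, `rsd_r`, `rsd_R`,
#'   `n_within_day`, `n_pooled`.
#' @export
precision_table <- function(concentrations, repeatability_day = NULL) {
  needed <- c("compound", "nominal_conc", "day", "replicate", "conc_ng_g")
  missing <- setdiff(needed, names(concentrations))
  if (length(missing) > 0) {
    abort(paste0("`concentrations` lacks columns: ",
                 paste(missing, collapse = ", ")),
          class = "residuval_schema_error")
  }
  counts <- concentrations %>%
    count(.data$compound, .data$nominal_conc, .data$day)
  if (is.null(repeatability_day)) {
    complete_days <- counts %>%
      group_by(.data$day) %>%
      summarise(ok = all(.data$n >= 2), .groups = "drop") %>%
      filter(.data$ok)
    if (nrow(complete_days) == 0) {
      gap <- counts %>% filter(.data$n < 2)
      abort(paste0("No day has >= 2 replicates everywhere; first gap: ",
                   gap$compound[1], " at ", gap$nominal_conc[1],
                   " ng/g, day ", gap$day[1]),
            class = "residuval_design_incompleteness_error")
    }
    repeatability_day <- min(complete_days$day)
  }
  incomplete <- counts %>%
    filter(.data$day == repeatability_day, .data$n < 2)
  if (nrow(incomplete) > 0) {
    abort(paste0("Repeatability day ", repeatability_day,
                 " lacks replicates for ", incomplete$compound[1], " at ",
                 incomplete$nominal_conc[1], " ng/g."),
          class = "residuval_design_incompleteness_error")
  }
  within <- concentrations %>%
    filter(.data$day == repeatability_day) %>%
    group_by(.data$compound, .data$nominal_conc) %>%
    summarise(rsd_r = rsd(.data$conc_ng_g), n_within_day = dplyr::n(),
              .groups = "drop")
  n_days <- n_distinct(concentrations$day)
  if (n_days < 2) {
    abort("Reproducibility needs results from at least 2 days.",
          class = "residuval_design_incompleteness_error")
  }
  pooled <- concentrations %>%
    group_by(.data$compound, .data$nominal_conc) %>%
    summarise(rsd_R = rsd(.data$conc_ng_g), n_pooled = dplyr::n(),
              .groups = "drop")
  inner_join(within, pooled, by = c("compound", "nominal_conc")) %>%
    select("compound", "nominal_conc", "rsd_r", "rsd_R",
           "n_within_day", "n_pooled")
}

#' Relative recovery (trueness)
#'
#' Quantified concentration over the spiked concentration, in percent.
#'
#' @param measured Quantified concentration(s), ng/g.
#' @param spiked Spiked (nominal) concentration(s), ng/g, > 0.
#' @return Percent recovery.
#' @examples
#' relative_recovery(5.02, 10) # 50.2
#' @export
relative_recovery <- function(measured, spiked) {
  if (any(spiked <= 0)) {
    abort("Spiked concentrations must be positive.",
          class = "residuval_validation_error")
  }
  100 * measured / spiked
}

#' Absolute recovery of an internal standard
#'
#' Extraction efficiency of an IL-IS spiked before extraction, referenced
#' to the TPP syringe standard spiked before injection:
#' `100 * (area_ilis / area_tpp) / cal_ratio`, where `cal_ratio` is the
#' same area ratio in the matrix-matched calibration standards (where
#' neither compound saw the extraction).
#'
#' @param area_ilis IL-IS peak area in the processed sample.
#' @param area_tpp TPP peak area in the same injection (> 0).
#' @param cal_ratio Mean `area_ilis / area_tpp` over the calibration
#'   standards (> 0).
#' @return Percent absolute recovery.
#' @export
absolute_recovery <- function(area_ilis, area_tpp, cal_ratio) {
  if (any(area_tpp <= 0) || any(cal_ratio <= 0)) {
    abort("`area_tpp` and `cal_ratio` must be positive.",
          class = "residuval_division_error")
  }
  100 * (area_ilis / area_tpp) / cal_ratio
}

#' Absolute recoveries of all internal standards in a dataset
#'
#' @param injections,samples A dataset containing calibration and
#'   processed (fortified/blank/monitoring) injections.
#' @param registry Compound registry (identifies IL-IS and TPP rows).
#' @return A tibble `compound`, `sample_id`, `nominal_conc`, `day`,
#'   `replicate`, `absolute_recovery_pct`.
#' @export
absolute_recoveries <- function(injections, samples, registry) {
  validate_registry(registry)
  tpp_name <- registry$name[registry$category == "syringe_standard"][1]
  ilis_names <- registry$name[registry$category == "internal_standard"]
  quant <- filter(injections, .data$transition_role == "quantifier")
  tpp <- quant %>%
    filter(.data$compound == tpp_name) %>%
    select("sample_id", tpp_area = "area")
  ratios <- quant %>%
    filter(.data$compound %in% ilis_names) %>%
    left_join(tpp, by = "sample_id") %>%
    inner_join(select(samples, "sample_id", "role", "nominal_conc", "day",
                      "replicate"), by = "sample_id")
  if (any(is.na(ratios$tpp_area) | ratios$tpp_area <= 0)) {
    abort("TPP area missing or non-positive in at least one injection.",
          class = "residuval_division_error")
  }
  cal_ratio <- ratios %>%
    filter(.data$role %in% c("solvent_cal", "mm_cal")) %>%
    group_by(.data$compound) %>%
    summarise(cal_ratio = mean(.data$area / .data$tpp_area), .groups = "drop")
  ratios %>%
    filter(.data$role %in% c("fortified", "blank", "monitoring")) %>%
    left_join(cal_ratio, by = "compound") %>%
    mutate(absolute_recovery_pct =
             absolute_recovery(.data$area, .data$tpp_area, .data$cal_ratio)) %>%
    select("compound", "sample_id", "nominal_conc", "day", "replicate",
           "absolute_recovery_pct")
}

#' Horwitz precision bounds
#'
#' Empirical between-laboratory precision `RSD_bl(%) = 2^(1 - 0.5 log10 C)`
#' as a function of the analyte mass fraction `C` (dimensionless; ng/g
#' corresponds to `C = x * 1e-9`), and the within-laboratory bound taken
#' as two-thirds of it.
#'
#' @param c_mass_fraction Dimensionless mass fraction(s), > 0.
#' @return A tibble `concentration`, `rsd_bl`, `rsd_wl` (percent).
#' @examples
#' horwitz(1e-8) # 10 ng/g: rsd_bl = 32%
#' @export
horwitz <- function(c_mass_fraction) {
  if (any(c_mass_fraction <= 0)) {
    abort("The Horwitz function is defined for positive mass fractions only.",
          class = "residuval_domain_error")
  }
  rsd_bl <- 2^(1 - 0.5 * log10(c_mass_fraction))
  tibble(concentration = c_mass_fraction, rsd_bl = rsd_bl,
         rsd_wl = (2 / 3) * rsd_bl)
}

#' Convert ng/g to the dimensionless mass fraction used by Horwitz
#' @param ng_g Concentration in ng/g.
#' @return Dimensionless mass fraction.
#' @export
ng_g_to_mass_fraction <- function(ng_g) ng_g * 1e-9

#' Determine the limit of quantification from a dilution series
#'
#' The LOQ is the lowest level whose quantifier transition has S/N
#' strictly above 10 and whose qualifier transition has S/N strictly
#' above 3, converted from extract units (ng/mL) to soil units (ng/g).
#'
#' @param snr_table A tibble `compound`, `level` (ng/mL), `snr_quant`,
#'   `snr_qual`.
#' @param policy A [units_policy()].
#' @param allow_missing If `TRUE`, compounds with no qualifying level get
#'   `NA` with a warning instead of an error.
#' @return A tibble `compound`, `loq_ng_g`.
#' @export
determine_loq <- function(snr_table, policy = units_policy(),
                          allow_missing = FALSE) {
  out <- snr_table %>%
    group_by(.data$compound) %>%
    arrange(.data$level, .by_group = TRUE) %>%
    summarise(
      loq_level = {
        ok <- .data$snr_quant > 10 & .data$snr_qual > 3
        if (any(ok)) min(.data$level[ok]) else NA_real_
      },
      .groups = "drop"
    )
  if (any(is.na(out$loq_level))) {
    who <- out$compound[is.na(out$loq_level)]
    msg <- paste0("No dilution level meets the S/N criteria for: ",
                  paste(who, collapse = ", "))
    if (allow_missing) warn(msg) else abort(msg, class = "residuval_no_loq_error")
  }
  out %>%
    mutate(loq_ng_g = to_ng_per_g(.data$loq_level, policy)) %>%
    select("compound", "loq_ng_g")
}

#' Extract a per-compound S/N table from dilution-series injections
#'
#' @param injections,samples A dilution series (e.g. from
#'   [simulate_dilution_series()]).
#' @param registry Compound registry; standards are excluded.
#' @return A tibble `compound`, `level`, `snr_quant`, `snr_qual`.
#' @export
snr_table <- function(injections, samples, registry) {
  analytes <- registry$name[!registry$category %in%
                              c("internal_standard", "syringe_standard")]
  injections %>%
    filter(.data$compound %in% analytes) %>%
    inner_join(select(samples, "sample_id", level = "nominal_conc"),
               by = "sample_id") %>%
    select("compound", "level", "transition_role", "snr") %>%
    tidyr::pivot_wider(names_from = "transition_role", values_from = "snr",
                       names_prefix = "snr_") %>%
    rename(snr_quant = "snr_quantifier", snr_qual = "snr_qualifier")
}

#' SANTE-style acceptance thresholds
#'
#' Default thresholds of the validation report: repeatability and
#' within-laboratory reproducibility RSD at most 20%, relative recovery
#' 70-120% (extended fit-for-purpose range 60-140%), calibration
#' R-squared above 0.99, and LOQ at most 50 ng/g (the acceptable LOQ for
#' pesticide residue analysis in soil).
#'
#' @param rsd_r_max,rsd_R_max Maximum acceptable RSDs (percent).
#' @param recovery_range,recovery_extended Acceptable mean-recovery
#'   windows (percent).
#' @param r_squared_min Minimum coefficient of determination.
#' @param loq_max Maximum acceptable LOQ (ng/g).
#' @return An object of class `sante_thresholds`.
#' @export
sante_thresholds <- function(rsd_r_max = 20, rsd_R_max = 20,
                             recovery_range = c(70, 120),
                             recovery_extended = c(60, 140),
                             r_squared_min = 0.99, loq_max = 50) {
  structure(list(rsd_r_max = rsd_r_max, rsd_R_max = rsd_R_max,
                 recovery_range = recovery_range,
                 recovery_extended = recovery_extended,
                 r_squared_min = r_squared_min, loq_max = loq_max),
            class = "sante_thresholds")
}

#' Build the per-compound validation report
#'
#' Combines precision, trueness, LOQ, and linearity into one row per
#' analyte mirroring the published validation-table layout (per-level RSDr,
#' RSDR, relative recovery in wide form) and flags each criterion against
#' the thresholds: every per-level RSDr and RSDR within bounds, mean
#' relative recovery inside the 70-120% (and extended 60-140%) window,
#' R-squared above the minimum, and LOQ at or below the ceiling.
#'
#' @param precision Output of [precision_table()].
#' @param recovery A tibble `compound`, `nominal_conc`, `rel_rec_pct`
#'   (per-level mean relative recovery).
#' @param loq Output of [determine_loq()].
#' @param linearity A tibble `compound`, `r_squared`.
#' @param registry Compound registry (category and IL-IS group columns).
#' @param thresholds A [sante_thresholds()].
#' @return A tibble with one row per analyte: identification columns,
#'   `rsdr_<level>`, `rsdR_<level>`, `rel_rec_<level>`, `loq_ng_g`,
#'   `r_squared`, and logical flags `rsdr_pass`, `rsdR_pass`,
#'   `recovery_pass`, `recovery_extended_pass`, `linearity_pass`,
#'   `loq_pass`.
#' @export
build_validation_report <- function(precision, recovery, loq, linearity,
                                    registry,
                                    thresholds = sante_thresholds()) {
  validate_registry(registry)
  wide_prec <- precision %>%
    select("compound", "nominal_conc", "rsd_r", "rsd_R") %>%
    tidyr::pivot_wider(names_from = "nominal_conc",
                       values_from = c("rsd_r", "rsd_R"),
                       names_glue = "{ifelse(.value == 'rsd_r', 'rsdr', 'rsdR')}_{nominal_conc}")
  wide_rec <- recovery %>%
    tidyr::pivot_wider(names_from = "nominal_conc",
                       values_from = "rel_rec_pct",
                       names_prefix = "rel_rec_")
  id_cols <- registry %>%
    filter(!.data$category %in% c("internal_standard", "syringe_standard")) %>%
    select(compound = "name", "category", "ilis_group", "si_ilis")
  report <- id_cols %>%
    inner_join(wide_prec, by = "compound") %>%
    inner_join(wide_rec, by = "compound") %>%
    inner_join(loq, by = "compound") %>%
    inner_join(linearity, by = "compound")
  rsdr_cols <- grep("^rsdr_", names(report), value = TRUE)
  rsdR_cols <- grep("^rsdR_", names(report), value = TRUE)
  rec_cols <- grep("^rel_rec_", names(report), value = TRUE)
  report %>%
    mutate(
      mean_recovery = rowMeans(across(all_of(rec_cols))),
      rsdr_pass = rowSums(across(all_of(rsdr_cols)) > thresholds$rsd_r_max) == 0,
      rsdR_pass = rowSums(across(all_of(rsdR_cols)) > thresholds$rsd_R_max) == 0,
      recovery_pass = .data$mean_recovery >= thresholds$recovery_range[1] &
        .data$mean_recovery <= thresholds$recovery_range[2],
      recovery_extended_pass =
        .data$mean_recovery >= thresholds$recovery_extended[1] &
        .data$mean_recovery <= thresholds$recovery_extended[2],
      linearity_pass = .data$r_squared > thresholds$r_squared_min,
      loq_pass = .data$loq_ng_g <= thresholds$loq_max
    )
}

#' Summary rows (mean, min, max) of a validation report
#'
#' Recomputes the aggregate rows printed under a validation table: the
#' mean, minimum, and maximum over compounds of every numeric figure of
#' merit.
#'
#' @param report A validation report (from [build_validation_report()] or
#'   [load_table2_fixture()]).
#' @return A tibble with rows `mean`, `min`, `max` and one column per
#'   numeric figure of merit.
#' @export
summarize_validation_report <- function(report) {
  stat_cols <- grep("^(rsdr_|rsdR_|rel_rec_|loq_ng_g$|r_squared$)",
                    names(report), value = TRUE)
  purrr::map_dfr(
    list(mean = mean, min = min, max = max),
    function(f) summarise(report, across(all_of(stat_cols), f)),
    .id = "statistic"
  )
}
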