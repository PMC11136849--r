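#' Selectivity checks: retention time and ion ratio
#'
#' An analyte identification is accepted when the observed retention time
#' lies within `rt_tol` minutes of the expected one (inclusive) and the
#' quantifier-to-qualifier area ratio lies within `ratio_tol` percent of
#' the ratio established by the matrix-matched calibration (inclusive).
#' The default +/-50% ratio window follows the soil-method convention; the
#' food/feed norm of +/-30% is available by setting `ratio_tol = 30`.
#'
#' @param rt Observed retention time (minutes).
#' @param expected_rt Expected retention time (minutes).
#' @param observed_ratio Observed quantifier/qualifier area ratio.
#' @param cal_ratio Calibration quantifier/qualifier ratio.
#' @param rt_tol Retention-time tolerance in minutes (default 0.5).
#' @param ratio_tol Relative ion-ratio tolerance in percent (default 50).
#' @return A tibble `rt_ok`, `ion_ratio_ok`.
#' @examples
#' selectivity_check(7.4, 7.0, 2.0, 2.0)
#' @export
selectivity_check <- function(rt, expected_rt, observed_ratio, cal_ratio,
                              rt_tol = 0.5, ratio_tol = 50) {
  if (any(is.na(observed_ratio))) {
    abort("Qualifier transition missing: identification is incomplete.",
          class = "residuval_incomplete_identification_error")
  }
  tibble(
    rt_ok = abs(rt - expected_rt) <= rt_tol,
    ion_ratio_ok = observed_ratio >= cal_ratio * (1 - ratio_tol / 100) &
      observed_ratio <= cal_ratio * (1 + ratio_tol / 100)
  )
}

#' Specificity check against procedural blanks
#'
#' A blank signal is acceptable when it is not higher than 30% of the LOQ
#' (non-strict comparison).
#'
#' @param blank_conc Blank concentration(s), ng/g.
#' @param loq LOQ(s), ng/g, > 0.
#' @return Logical vector.
#' @export
specificity_check <- function(blank_conc, loq) {
  if (any(loq <= 0)) {
    abort("LOQ must be positive.", class = "residuval_validation_error")
  }
  blank_conc <= 0.3 * loq
}

#' Blank-referenced reporting rule
#'
#' For compounds flagged as blank-contaminated (e.g. a transformation
#' product that shows a peak in unspiked control soil), a concentration is
#' only reported when it exceeds every concurrently processed blank;
#' otherwise it is censored. Unflagged compounds bypass the rule.
#'
#' @param conc Concentration(s) to report, ng/g.
#' @param batch_blank_concs Concentrations of the batch's blank samples
#'   (sand and blank soil), ng/g.
#' @param flagged Is the compound subject to blank referencing?
#' @return A tibble `conc_ng_g`, `reported`, `censor_reason`.
#' @export
blank_referenced_report <- function(conc, batch_blank_concs, flagged = TRUE) {
  if (!flagged) {
    return(tibble(conc_ng_g = conc, reported = TRUE,
                  censor_reason = NA_character_))
  }
  if (length(batch_blank_concs) == 0) {
    abort("A blank-flagged compound needs at least one batch blank.",
          class = "residuval_missing_blank_error")
  }
  ok <- conc > max(batch_blank_concs)
  tibble(conc_ng_g = conc, reported = ok,
         censor_reason = ifelse(ok, NA_character_, "not_above_blanks"))
}

#' Screen a monitoring batch
#'
#' Applies the full QA/QC chain to quantified monitoring samples: the
#' retention-time and ion-ratio selectivity checks on the raw injections,
#' the LOQ cut, and blank referencing for flagged compounds. A
#' concentration is reported only when all checks pass.
#'
#' @param injections Injection records of the monitoring batch.
#' @param samples Sample metadata (roles `monitoring` and `blank`).
#' @param curves Curve tibble from [fit_curves()] (internal mode) used for
#'   quantification and for the calibration ion ratios.
#' @param registry Compound registry.
#' @param loq LOQ table from [determine_loq()].
#' @param blank_flagged Character vector of compounds subject to blank
#'   referencing.
#' @param rt_tol,ratio_tol Selectivity tolerances (see
#'   [selectivity_check()]).
#' @param fallback_matrix Calibration matrix used for quantification.
#' @param cal_injections,cal_samples The calibration dataset the batch was
#'   calibrated with, used to derive the reference quantifier/qualifier ion
#'   ratios; defaults to `injections`/`samples` when the batch file already
#'   contains its calibration series.
#' @param policy A [units_policy()].
#' @return A tibble `sample_id`, `compound`, `conc_ng_g`, `rt_ok`,
#'   `ion_ratio_ok`, `above_loq`, `blank_ok`, `reported_conc` (NA when
#'   censored).
#' @export
screen_samples <- function(injections, samples, curves, registry, loq,
                           blank_flagged = character(),
                           rt_tol = 0.5, ratio_tol = 50,
                           fallback_matrix = "SR",
                           cal_injections = injections,
                           cal_samples = samples,
                           policy = units_policy()) {
  validate_registry(registry)
  conc <- quantify_samples(injections, samples, curves, registry,
                           mode = "internal",
                           roles = c("monitoring", "blank"),
                           fallback_matrix = fallback_matrix,
                           policy = policy)
  blanks <- conc %>%
    filter(.data$role == "blank") %>%
    group_by(.data$compound) %>%
    summarise(max_blank = max(.data$conc_ng_g), .groups = "drop")
  mon <- filter(conc, .data$role == "monitoring")

  # observed quantifier/qualifier ratio and RT per sample-compound
  areas <- injections %>%
    semi_join(filter(samples, .data$role == "monitoring"), by = "sample_id") %>%
    select("sample_id", "compound", "transition_role", "area", "rt") %>%
    tidyr::pivot_wider(names_from = "transition_role",
                       values_from = c("area", "rt")) %>%
    mutate(observed_ratio = ifelse(.data$area_qualifier > 0,
                                   .data$area_quantifier / .data$area_qualifier,
                                   NA_real_))
  # calibration ion ratio: quantifier/qualifier over the matched matrix curves
  cal_ratio <- calibration_ion_ratios(cal_injections, cal_samples)
  rt_expect <- registry %>% select(compound = "name", "expected_rt")

  screened <- mon %>%
    left_join(areas, by = c("sample_id", "compound")) %>%
    left_join(cal_ratio, by = "compound") %>%
    left_join(rt_expect, by = "compound") %>%
    left_join(loq, by = "compound") %>%
    left_join(blanks, by = "compound") %>%
    mutate(
      rt_ok = !is.na(.data$rt_quantifier) &
        abs(.data$rt_quantifier - .data$expected_rt) <= rt_tol,
      ion_ratio_ok = !is.na(.data$observed_ratio) & !is.na(.data$cal_ratio) &
        .data$observed_ratio >= .data$cal_ratio * (1 - ratio_tol / 100) &
        .data$observed_ratio <= .data$cal_ratio * (1 + ratio_tol / 100),
      above_loq = .data$conc_ng_g >= .data$loq_ng_g,
      blank_ok = ifelse(.data$compound %in% blank_flagged,
                        .data$conc_ng_g > dplyr::coalesce(.data$max_blank, 0),
                        TRUE),
      all_ok = .data$rt_ok & .data$ion_ratio_ok & .data$above_loq & .data$blank_ok,
      reported_conc = ifelse(.data$all_ok, .data$conc_ng_g, NA_real_)
    ) %>%
    select("sample_id", "compound", "conc_ng_g", "rt_ok", "ion_ratio_ok",
           "above_loq", "blank_ok", "reported_conc")
  screened
}

# mean quantifier/qualifier area ratio over calibration injections
calibration_ion_ratios <- function(injections, samples) {
  cal <- injections %>%
    semi_join(filter(samples, .data$role %in% c("solvent_cal", "mm_cal"),
                     .data$nominal_conc > 0), by = "sample_id")
  if (nrow(cal) == 0) {
    abort("No calibration injections available to derive ion ratios from; pass `cal_injections`/`cal_samples`.",
          class = "residuval_pairing_error")
  }
  cal %>%
    select("sample_id", "compound", "transition_role", "area") %>%
    tidyr::pivot_wider(names_from = "transition_role", values_from = "area") %>%
    filter(.data$qualifier > 0) %>%
    group_by(.data$compound) %>%
    summarise(cal_ratio = mean(.data$quantifier / .data$qualifier),
              .groups = "drop")
}

#' Occurrence summary of a screened batch
#'
#' Detection frequency and concentration statistics per compound, where
#' "detected" means a reported (post-screen) concentration at or above the
#' LOQ; censored or sub-LOQ signals count as non-detects.
#'
#' @param screened Output of [screen_samples()].
#' @return A tibble `compound`, `n_samples`, `n_detects`,
#'   `detection_frequency` (percent), `median_conc`, `max_conc` (over
#'   detects; NA when none).
#' @export
summarize_occurrence <- function(screened) {
  if (nrow(screened) == 0) {
    abort("Cannot summarize an empty batch.",
          class = "residuval_empty_input_error")
  }
  screened %>%
    group_by(.data$compound) %>%
    summarise(
      n_samples = n_distinct(.data$sample_id),
      n_detects = sum(!is.na(.data$reported_conc)),
      detection_frequency = 100 * .data$n_detects / .data$n_samples,
      median_conc = if (any(!is.na(.data$reported_conc))) {
        median(.data$reported_conc, na.rm = TRUE)
      } else NA_real_,
      max_conc = if (any(!is.na(.data$reported_conc))) {
        max(.data$reported_conc, na.rm = TRUE)
      } else NA_real_,
      .groups = "drop"
    )
}

#' Batch-level detection statistics
#'
#' @param screened Output of [screen_samples()].
#' @param k Co-occurrence threshold (default 3 residues).
#' @return A one-row tibble `n_samples`, `frac_with_detect` (fraction of
#'   samples with at least one reported residue), `frac_cooccurrence_k`
#'   (fraction with >= `k` residues), `median_detect_count`.
#' @export
batch_stats <- function(screened, k = 3) {
  per_sample <- screened %>%
    group_by(.data$sample_id) %>%
    summarise(n_detect = sum(!is.na(.data$reported_conc)), .groups = "drop")
  tibble(
    n_samples = nrow(per_sample),
    frac_with_detect = mean(per_sample$n_detect >= 1),
    frac_cooccurrence_k = mean(per_sample$n_detect >= k),
    median_detect_count = median(per_sample$n_detect)
  )
}

#' Per-sample residue sums
#'
#' Sums reported (post-screen) concentrations per sample; censored values
#' contribute zero.
#'
#' @param screened Output of [screen_samples()].
#' @return A tibble `sample_id`, `residue_sum` (ng/g dry weight).
#' @export
residue_sums <- function(screened) {
  screened %>%
    group_by(.data$sample_id) %>%
    summarise(residue_sum = sum(.data$reported_conc, na.rm = TRUE),
              .groups = "drop")
}

#' Sum-exceedance report against soil guidance limits
#'
#' Counts samples whose summed residues strictly exceed each threshold
#' (a sum exactly at the limit does not exceed it).
#'
#' @param screened Output of [screen_samples()], or a tibble with
#'   `sample_id` and `residue_sum`.
#' @param thresholds Named numeric vector of limits in ng/g (defaults to
#'   the Czech 100 ng/g and Netherlands 70 ng/g guidance values).
#' @return A tibble `limit`, `threshold_ng_g`, `n_exceeding`,
#'   `fraction_exceeding`.
#' @export
exceedance <- function(screened,
                       thresholds = c(czech = 100, netherlands = 70)) {
  if (any(thresholds <= 0)) {
    abort("Thresholds must be positive.", class = "residuval_validation_error")
  }
  sums <- if ("residue_sum" %in% names(screened)) {
    screened
  } else {
    residue_sums(screened)
  }
  purrr::imap_dfr(thresholds, function(th, nm) {
    tibble(limit = nm, threshold_ng_g = th,
           n_exceeding = sum(sums$residue_sum > th),
           fraction_exceeding = mean(sums$residue_sum > th))
  })
}
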