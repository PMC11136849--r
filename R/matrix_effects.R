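#' Matrix effect from calibration slopes
#'
#' The matrix effect is the percent deviation of the matrix-matched
#' calibration slope from the solvent calibration slope,
#' `ME = (slope_mm / slope_solvent - 1) * 100`. Following the SANTE
#' convention, `|ME| > 20%` is significant: values below -20 are
#' suppression, above +20 enhancement, and everything else (boundaries
#' included) non-significant.
#'
#' @param slope_mm Slope(s) of the matrix-matched calibration.
#' @param slope_solvent Slope(s) of the solvent calibration (> 0).
#' @return A tibble `me_pct`, `classification`.
#' @examples
#' matrix_effect(2, 1)   # +100%, enhancement
#' matrix_effect(0.5, 1) # -50%, suppression
#' @export
matrix_effect <- function(slope_mm, slope_solvent) {
  if (any(is.na(slope_solvent) | slope_solvent <= 0)) {
    abort("Matrix effect is undefined for non-positive solvent slopes.",
          class = "residuval_undefined_me_error")
  }
  me <- (slope_mm / slope_solvent - 1) * 100
  tibble(me_pct = me, classification = classify_me(me))
}

classify_me <- function(me_pct, threshold = 20) {
  case_when(
    me_pct < -threshold ~ "suppression",
    me_pct > threshold ~ "enhancement",
    TRUE ~ "nonsignificant"
  )
}

#' Matrix effects for a full curve table
#'
#' Compares every non-solvent curve against the solvent curve of the same
#' compound and mode. Curves fitted on different level sets are not
#' compared (an error is raised), since their slopes are not exchangeable.
#'
#' @param curves A curve tibble from [fit_curves()] containing solvent and
#'   matrix-matched curves.
#' @return A tibble `compound`, `matrix`, `mode`, `me_pct`,
#'   `classification`.
#' @export
matrix_effects <- function(curves) {
  solvent <- curves %>%
    filter(.data$matrix == "solvent") %>%
    select("compound", "mode", solvent_slope = "slope",
           solvent_n = "n_points")
  mm <- filter(curves, .data$matrix != "solvent")
  joined <- inner_join(mm, solvent, by = c("compound", "mode"))
  if (nrow(joined) == 0) {
    abort("Need both solvent and matrix-matched curves to compute matrix effects.",
          class = "residuval_validation_error")
  }
  if (any(joined$n_points != joined$solvent_n)) {
    abort("Matrix-matched and solvent curves were fitted on different level sets; refit on a common design.",
          class = "residuval_validation_error")
  }
  joined %>%
    mutate(me_pct = (.data$slope / .data$solvent_slope - 1) * 100,
           classification = classify_me(.data$me_pct)) %>%
    select("compound", "matrix", "mode", "me_pct", "classification")
}

#' Compare two calibration slopes (t-test, unequal variances)
#'
#' Tests the null hypothesis that two calibration slopes are equal using
#' `t = (b1 - b2) / sqrt(s2_b1 + s2_b2)` with the slope variances taken
#' from the individual regressions, referred to a t distribution with
#' `n1 + n2 - 4` degrees of freedom (two parameters estimated per
#' regression). The test is two-sided: the hypothesis is equality, with no
#' direction implied.
#'
#' @param c1,c2 Curves for the same compound and mode (as `resid_curve`
#'   objects or one-row tibbles from [fit_curves()]).
#' @param alpha Significance level (default 0.05).
#' @return A tibble `compound`, `matrix_1`, `matrix_2`, `t_stat`, `df`,
#'   `p_value`, `reject_h0`.
#' @export
compare_slopes <- function(c1, c2, alpha = 0.05) {
  f <- function(x, field) {
    if (inherits(x, "resid_curve")) x[[field]] else x[[field]][1]
  }
  if (!identical(f(c1, "compound"), f(c2, "compound")) ||
      !identical(f(c1, "mode"), f(c2, "mode"))) {
    abort("Slopes can only be compared for the same compound and calibration mode.",
          class = "residuval_comparison_error")
  }
  n1 <- f(c1, "n_points"); n2 <- f(c2, "n_points")
  if (n1 < 3 || n2 < 3) {
    abort("Both curves need at least 3 points for a slope comparison.",
          class = "residuval_insufficient_data_error")
  }
  se <- sqrt(f(c1, "slope_variance") + f(c2, "slope_variance"))
  t_stat <- if (se == 0) {
    if (f(c1, "slope") == f(c2, "slope")) 0 else Inf * sign(f(c1, "slope") - f(c2, "slope"))
  } else {
    (f(c1, "slope") - f(c2, "slope")) / se
  }
  df <- n1 + n2 - 4
  p <- 2 * pt(-abs(t_stat), df)
  tibble(compound = f(c1, "compound"),
         matrix_1 = f(c1, "matrix"), matrix_2 = f(c2, "matrix"),
         t_stat = t_stat, df = df, p_value = p,
         reject_h0 = p < alpha)
}

#' Slope comparisons of one reference matrix against all others
#'
#' @param curves A curve tibble from [fit_curves()].
#' @param reference_matrix Matrix whose curves are `b1` in every
#'   comparison (default the validation soil `"SR"`).
#' @param alpha Significance level.
#' @param mode Calibration mode to compare within.
#' @return A tibble of [compare_slopes()] rows, one per (compound, other
#'   matrix).
#' @export
slope_comparisons <- function(curves, reference_matrix = "SR", alpha = 0.05,
                              mode = "internal") {
  cm <- filter(curves, .data$mode == !!mode)
  ref <- filter(cm, .data$matrix == reference_matrix)
  others <- filter(cm, !.data$matrix %in% c(reference_matrix, "solvent")) %>%
    semi_join(ref, by = "compound")
  purrr::map_dfr(seq_len(nrow(others)), function(i) {
    o <- others[i, ]
    r <- ref[ref$compound == o$compound, ][1, ]
    compare_slopes(r, o, alpha = alpha)
  })
}

#' Summarize a matrix-effect distribution
#'
#' Mean, sample SD, linear-interpolation quartiles, extrema, and counts of
#' significant effects per (matrix, mode), optionally restricted to
#' compounds with (or without) a structure-identical IL-IS.
#'
#' @param results A tibble from [matrix_effects()].
#' @param registry Optional registry used to resolve the si/nsi subgroups.
#' @param subgroup `"all"`, `"si_ilis"`, or `"nsi_ilis"`.
#' @return A tibble `matrix`, `mode`, `subgroup`, `mean`, `std`, `q1`,
#'   `median`, `q3`, `min`, `max`, `n_significant`, `n_total`.
#' @export
summarize_me <- function(results, registry = NULL,
                         subgroup = c("all", "si_ilis", "nsi_ilis")) {
  subgroup <- match.arg(subgroup)
  if (nrow(results) == 0) {
    abort("Cannot summarize an empty matrix-effect table.",
          class = "residuval_empty_input_error")
  }
  if (subgroup != "all") {
    if (is.null(registry)) {
      abort("`registry` is required to resolve si/nsi subgroups.",
            class = "residuval_validation_error")
    }
    si <- registry %>%
      filter(!.data$category %in% c("internal_standard", "syringe_standard"),
             if (subgroup == "si_ilis") .data$si_ilis else !.data$si_ilis)
    results <- semi_join(results, tibble(compound = si$name), by = "compound")
    if (nrow(results) == 0) {
      abort("No matrix-effect results left in the requested subgroup.",
            class = "residuval_empty_input_error")
    }
  }
  results %>%
    group_by(.data$matrix, .data$mode) %>%
    summarise(
      subgroup = subgroup,
      mean = mean(.data$me_pct),
      std = sd(.data$me_pct),
      q1 = unname(quantile(.data$me_pct, 0.25, type = 7)),
      median = median(.data$me_pct),
      q3 = unname(quantile(.data$me_pct, 0.75, type = 7)),
      min = min(.data$me_pct),
      max = max(.data$me_pct),
      n_significant = sum(abs(.data$me_pct) > 20),
      n_total = dplyr::n(),
      .groups = "drop"
    )
}
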