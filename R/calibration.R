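#' Assemble calibration response points
#'
#' Turns calibration injections into the (level, response) points that
#' calibration curves are fitted on. In external mode the response is the
#' analyte's quantifier peak area; in internal mode it is the quantifier
#' area divided by the quantifier area of the IL-IS assigned to the
#' analyte's IL-IS group in the same injection. Replicated levels stay
#' individual points (they are not averaged), which preserves the slope
#' variance needed for slope-comparison testing. The zero level never
#' appears because calibration samples are generated/recorded from 5 ng/mL
#' up.
#'
#' @param injections Injection records (see [read_injections()]).
#' @param samples Sample metadata (see [read_samples()]).
#' @param registry Compound registry.
#' @param mode `"internal"` (IL-IS normalized, the routine method) or
#'   `"external"` (raw areas).
#' @param levels Optional subset of calibration levels to use.
#' @return A tibble `compound`, `matrix`, `mode`, `level`, `response`.
#' @export
build_response_points <- function(injections, samples, registry,
                                  mode = c("internal", "external"),
                                  levels = NULL) {
  mode <- match.arg(mode)
  validate_registry(registry)
  cal_samples <- samples %>%
    filter(.data$role %in% c("solvent_cal", "mm_cal"), .data$nominal_conc > 0)
  if (!is.null(levels)) {
    cal_samples <- filter(cal_samples, .data$nominal_conc %in% levels)
  }
  assign_tbl <- ilis_assignment(registry)
  quant <- injections %>%
    filter(.data$transition_role == "quantifier") %>%
    semi_join(cal_samples, by = "sample_id") %>%
    inner_join(select(cal_samples, "sample_id", "matrix",
                      level = "nominal_conc"),
               by = "sample_id")
  analyte_areas <- quant %>%
    semi_join(tibble(compound = assign_tbl$compound), by = "compound")

  if (mode == "external") {
    out <- analyte_areas %>% mutate(response = .data$area)
  } else {
    ilis_areas <- quant %>%
      inner_join(tibble(ilis_name = assign_tbl$ilis_name) %>% distinct(),
                 by = c(compound = "ilis_name")) %>%
      select("sample_id", ilis_name = "compound", ilis_area = "area")
    out <- analyte_areas %>%
      left_join(select(assign_tbl, "compound", "ilis_name"), by = "compound") %>%
      left_join(ilis_areas, by = c("sample_id", "ilis_name"))
    missing <- out %>% filter(is.na(.data$ilis_area))
    if (nrow(missing) > 0) {
      abort(paste0("No IL-IS area for ", missing$ilis_name[1],
                   " in sample ", missing$sample_id[1],
                   " (and possibly others); internal mode needs the IL-IS in every calibration injection."),
            class = "residuval_pairing_error")
    }
    zero <- out %>% filter(.data$ilis_area == 0)
    if (nrow(zero) > 0) {
      abort(paste0("IL-IS area is zero in sample ", zero$sample_id[1],
                   "; cannot form area ratios."),
            class = "residuval_division_error")
    }
    out <- mutate(out, response = .data$area / .data$ilis_area)
  }
  out %>%
    mutate(mode = mode) %>%
    select("compound", "matrix", "mode", "level", "response") %>%
    arrange(.data$compound, .data$matrix, .data$level)
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of response on concentration with an intercept -
#' the curve is deliberately not forced through the origin. Returns the
#' slope, intercept, the standard OLS variance of the slope estimator
#' (the ingredient of the slope-comparison t-test), and R-squared computed
#' as 1 - SSR/SST on the fitted points.
#'
#' @param points A tibble with columns `level` and `response` (one
#'   compound/matrix worth of points).
#' @param compound,matrix,mode Metadata carried on the returned curve;
#'   taken from `points` when present.
#' @return An object of class `resid_curve` with fields `compound`,
#'   `matrix`, `mode`, `slope`, `intercept`, `slope_variance`,
#'   `r_squared`, `n_points`, `residual_sd`.
#' @examples
#' pts <- tibble::tibble(level = c(5, 10, 25, 50), response = c(11, 21, 51, 101))
#' fit_curve(pts)
#' @export
fit_curve <- function(points, compound = NULL, matrix = NULL, mode = NULL) {
  compound <- compound %||% unique(points[["compound"]]) %||% NA_character_
  matrix <- matrix %||% unique(points[["matrix"]]) %||% NA_character_
  mode <- mode %||% unique(points[["mode"]]) %||% NA_character_
  lev <- points$level
  resp <- points$response
  if (any(lev <= 0)) {
    abort("Calibration levels must be positive (the zero level is excluded from fitting).",
          class = "residuval_validation_error")
  }
  if (!all(is.finite(resp))) {
    abort("Calibration responses must be finite.",
          class = "residuval_validation_error")
  }
  if (length(unique(lev)) < 3) {
    abort("At least 3 distinct calibration levels are required.",
          class = "residuval_insufficient_data_error")
  }
  if (sd(lev) == 0) {
    abort("Degenerate design: calibration levels have zero variance.",
          class = "residuval_degenerate_design_error")
  }
  fit <- lm(resp ~ lev)
  b <- unname(coef(fit)[2])
  a <- unname(coef(fit)[1])
  n <- length(resp)
  res <- resp - (a + b * lev)
  sst <- sum((resp - mean(resp))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(res^2) / sst
  # OLS slope variance: s^2 / Sxx (0 for an exact fit)
  sxx <- sum((lev - mean(lev))^2)
  s2 <- sum(res^2) / (n - 2)
  structure(
    list(compound = compound[1], matrix = matrix[1], mode = mode[1],
         slope = b, intercept = a, slope_variance = s2 / sxx,
         r_squared = max(0, min(1, r2)), n_points = n,
         residual_sd = sqrt(s2)),
    class = "resid_curve"
  )
}

#' Fit calibration curves for every compound and matrix
#'
#' @param points Response points from [build_response_points()].
#' @return A tibble with one row per (compound, matrix, mode) and the
#'   fields of [fit_curve()].
#' @export
fit_curves <- function(points) {
  points %>%
    group_by(.data$compound, .data$matrix, .data$mode) %>%
    tidyr::nest(data = c("level", "response")) %>%
    ungroup() %>%
    mutate(curve = purrr::pmap(list(.data$data, .data$compound, .data$matrix,
                                    .data$mode), fit_curve)) %>%
    mutate(fields = purrr::map(.data$curve, ~ as_tibble(unclass(.x)[
      c("slope", "intercept", "slope_variance", "r_squared",
        "n_points", "residual_sd")]))) %>%
    select("compound", "matrix", "mode", "fields") %>%
    tidyr::unnest("fields")
}

#' Invert a calibration curve
#'
#' Back-calculates the soil concentration from an instrument response:
#' `(response - intercept) / slope` in extract units, then converted to
#' ng/g with the units policy. Negative back-calculated concentrations
#' (possible for blanks when the intercept is positive) are clipped to
#' zero and flagged rather than rejected.
#'
#' @param curve A `resid_curve`, or a one-row tibble with `slope` and
#'   `intercept`.
#' @param response Numeric vector of responses.
#' @param policy A [units_policy()].
#' @return A tibble `response`, `conc_ng_g`, `clipped`.
#' @examples
#' crv <- fit_curve(tibble::tibble(level = c(5, 10, 25, 50),
#'                                 response = c(11, 21, 51, 101)))
#' quantify(crv, 51)
#' @export
quantify <- function(curve, response, policy = units_policy()) {
  slope <- if (inherits(curve, "resid_curve")) curve$slope else curve$slope[1]
  intercept <- if (inherits(curve, "resid_curve")) curve$intercept else curve$intercept[1]
  if (is.na(slope) || slope <= 0) {
    abort("Unusable curve: slope must be positive to invert.",
          class = "residuval_unusable_curve_error")
  }
  conc_extract <- (response - intercept) / slope
  clipped <- conc_extract < 0
  conc_extract[clipped] <- 0
  tibble(response = response,
         conc_ng_g = to_ng_per_g(conc_extract, policy),
         clipped = clipped)
}

#' Quantify processed samples against fitted curves
#'
#' Pipeline convenience: forms internal- or external-mode responses for
#' every fortified/blank/monitoring sample and inverts the matching
#' (compound, matrix, mode) curve. Samples in matrices without a curve in
#' that matrix fall back to the curve of `fallback_matrix` (routine
#' batches are quantified against one matrix-matched calibration soil).
#'
#' @inheritParams build_response_points
#' @param curves A curve tibble from [fit_curves()].
#' @param roles Sample roles to quantify.
#' @param fallback_matrix Matrix whose curve quantifies samples lacking a
#'   matrix-specific curve (default `"SR"`).
#' @param policy A [units_policy()].
#' @return A tibble `sample_id`, `compound`, `matrix`, `role`,
#'   `nominal_conc`, `day`, `replicate`, `conc_ng_g`, `clipped`.
#' @export
quantify_samples <- function(injections, samples, curves, registry,
                             mode = c("internal", "external"),
                             roles = c("fortified", "blank", "monitoring"),
                             fallback_matrix = "SR",
                             policy = units_policy()) {
  mode <- match.arg(mode)
  validate_registry(registry)
  target <- filter(samples, .data$role %in% roles)
  assign_tbl <- ilis_assignment(registry)
  quant <- injections %>%
    filter(.data$transition_role == "quantifier") %>%
    semi_join(target, by = "sample_id")
  analyte_areas <- quant %>% semi_join(tibble(compound = assign_tbl$compound),
                                       by = "compound")
  if (mode == "internal") {
    ilis_areas <- quant %>%
      inner_join(distinct(tibble(ilis_name = assign_tbl$ilis_name)),
                 by = c(compound = "ilis_name")) %>%
      select("sample_id", ilis_name = "compound", ilis_area = "area")
    responses <- analyte_areas %>%
      left_join(select(assign_tbl, "compound", "ilis_name"), by = "compound") %>%
      left_join(ilis_areas, by = c("sample_id", "ilis_name"))
    if (any(is.na(responses$ilis_area) | responses$ilis_area == 0)) {
      bad <- responses$sample_id[is.na(responses$ilis_area) |
                                   responses$ilis_area == 0][1]
      abort(paste0("Missing or zero IL-IS area in sample ", bad, "."),
            class = "residuval_pairing_error")
    }
    responses <- mutate(responses, response = .data$area / .data$ilis_area)
  } else {
    responses <- mutate(analyte_areas, response = .data$area)
  }
  curves_mode <- filter(curves, .data$mode == !!mode)
  responses <- responses %>%
    inner_join(select(target, "sample_id", "matrix", "role", "nominal_conc",
                      "day", "replicate"),
               by = "sample_id") %>%
    left_join(select(curves_mode, "compound", "matrix", "slope", "intercept"),
              by = c("compound", "matrix"))
  fb <- curves_mode %>%
    filter(.data$matrix == fallback_matrix) %>%
    select("compound", fb_slope = "slope", fb_intercept = "intercept")
  responses <- responses %>%
    left_join(fb, by = "compound") %>%
    mutate(slope = ifelse(is.na(.data$slope), .data$fb_slope, .data$slope),
           intercept = ifelse(is.na(.data$intercept), .data$fb_intercept,
                              .data$intercept))
  if (any(is.na(responses$slope))) {
    abort(paste0("No calibration curve for compound ",
                 responses$compound[is.na(responses$slope)][1], "."),
          class = "residuval_unusable_curve_error")
  }
  if (any(responses$slope <= 0)) {
    abort(paste0("Unusable curve (slope <= 0) for ",
                 responses$compound[responses$slope <= 0][1], "."),
          class = "residuval_unusable_curve_error")
  }
  responses %>%
    mutate(conc_extract = (.data$response - .data$intercept) / .data$slope,
           clipped = .data$conc_extract < 0,
           conc_ng_g = to_ng_per_g(pmax(.data$conc_extract, 0), policy)) %>%
    select("sample_id", "compound", "matrix", "role", "nominal_conc",
           "day", "replicate", "conc_ng_g", "clipped")
}
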