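#' Study design for simulated validation experiments
#'
#' Captures the experimental design the simulator reproduces: six-point
#' matrix-matched calibration (5-100 ng/mL, the zero level never enters
#' fitting), fortification at 10/25/50 ng/g in quadruplicate on three days,
#' five soil matrices plus solvent, and 10 ng/g nominal levels for the
#' IL-IS mixture (spiked before extraction) and the TPP syringe standard
#' (spiked before injection).
#'
#' @param calibration_levels Calibration levels in ng/mL (zero excluded).
#' @param fortification_levels Fortification levels in ng/g.
#' @param replicates_per_level Fortified replicates per (level, day).
#' @param days Number of validation days.
#' @param matrices Matrices to calibrate in; must include `"solvent"` for
#'   matrix-effect work.
#' @param cal_replicates Replicate injections per calibration level.
#' @param validation_matrix Soil used for the precision/trueness design.
#' @param blanks_per_day Procedural blanks per day in the validation soil.
#' @param ilis_nominal,tpp_nominal Nominal IL-IS and TPP levels (ng/g,
#'   equivalently ng/mL at the default 1 mL/g policy).
#' @param loq_levels Dilution-series levels (ng/mL) for LOQ determination.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(calibration_levels = c(5, 10, 25, 50, 75, 100),
                        fortification_levels = c(10, 25, 50),
                        replicates_per_level = 4,
                        days = 3,
                        matrices = c("solvent", "SR", "RFNo", "RFNc", "XFN", "DC"),
                        cal_replicates = 3,
                        validation_matrix = "SR",
                        blanks_per_day = 1,
                        ilis_nominal = 10,
                        tpp_nominal = 10,
                        loq_levels = c(0.1, 0.25, 0.5, 1, 5, 10, 25, 50, 75, 100)) {
  if (any(calibration_levels <= 0)) {
    abort("Calibration levels must be positive; the zero level never enters fitting.",
          class = "residuval_validation_error")
  }
  if (replicates_per_level < 2) {
    abort("At least 2 replicates per level are required for any precision statistic.",
          class = "residuval_validation_error")
  }
  if (!validation_matrix %in% matrices) {
    abort("`validation_matrix` must be one of `matrices`.",
          class = "residuval_validation_error")
  }
  structure(
    list(calibration_levels = sort(unique(calibration_levels)),
         fortification_levels = sort(unique(fortification_levels)),
         replicates_per_level = replicates_per_level, days = days,
         matrices = matrices, cal_replicates = cal_replicates,
         validation_matrix = validation_matrix,
         blanks_per_day = blanks_per_day,
         ilis_nominal = ilis_nominal, tpp_nominal = tpp_nominal,
         loq_levels = sort(unique(loq_levels))),
    class = "design_spec"
  )
}

#' Ground-truth ledger for the peak-area simulator
#'
#' Draws (or accepts) the true per-compound parameters behind simulated
#' peak areas: detector response factors, per-(compound, matrix)
#' multiplicative matrix-enhancement factors (1 in pure solvent),
#' extraction recoveries, a shared per-day lognormal scale, the injection
#' CV, per-compound blank contamination, and the fixed
#' quantifier-to-qualifier ion ratio. Structure-identical IL-IS share their
#' analyte's matrix factor and extraction recovery exactly (they are the
#' same molecule up to isotopes); non-structure-identical standards get
#' their own draws - this asymmetry is what makes internal-standard matrix
#' effects collapse for si pairs but not in general.
#'
#' Default matrix-factor base levels per soil are anchored to the mean
#' external-mode matrix enhancements observed for the five reference soils
#' (skeletic regosol the strongest at about +146%, organically managed
#' rhodic ferralic nitisol the mildest at about +34%), with a lognormal
#' compound-to-compound spread.
#'
#' @param registry A compound registry.
#' @param seed Integer seed; the ledger and every simulation derived from
#'   it are reproducible given this seed.
#' @param response_factor Optional named vector (area units per ng/mL)
#'   overriding the lognormal default draws.
#' @param extraction_recovery Optional named vector of fractions in (0, 1].
#' @param matrix_factor Optional tibble `name`, `matrix`, `matrix_factor`
#'   overriding the default draws.
#' @param matrix_base Named base enhancement factor per soil matrix.
#' @param matrix_spread_sdlog Lognormal sd of the compound-level spread
#'   around `matrix_base`.
#' @param day_effect_sd Lognormal scale of the shared per-day multiplier.
#' @param injection_cv Coefficient of variation of multiplicative
#'   injection noise (fraction, e.g. 0.05).
#' @param blank_level Optional named vector of blank contamination levels
#'   in ng/g (default 0 for every compound).
#' @param ion_ratio Fixed qualifier/quantifier ion ratio per compound
#'   (scalar recycled, or named vector).
#' @param ion_ratio_cv Relative noise of the qualifier ion ratio.
#' @param noise_floor Baseline-noise area used to emit S/N as
#'   `area / noise_floor`; no chromatogram is simulated.
#' @return An object of class `ground_truth`.
#' @examples
#' reg <- soil_pesticide_registry()
#' truth <- ground_truth(reg, seed = 1)
#' head(truth$compounds)
#' @export
ground_truth <- function(registry, seed = 1,
                         response_factor = NULL,
                         extraction_recovery = NULL,
                         matrix_factor = NULL,
                         matrix_base = c(SR = 2.46, RFNo = 1.34, RFNc = 1.89,
                                         XFN = 2.15, DC = 2.36),
                         matrix_spread_sdlog = 0.4,
                         day_effect_sd = 0.1,
                         injection_cv = 0.05,
                         blank_level = NULL,
                         ion_ratio = 0.5,
                         ion_ratio_cv = 0.05,
                         noise_floor = 5) {
  validate_registry(registry)
  if (injection_cv < 0 || day_effect_sd < 0 || ion_ratio_cv < 0) {
    abort("Noise parameters (`injection_cv`, `day_effect_sd`, `ion_ratio_cv`) must be >= 0.",
          class = "residuval_validation_error")
  }
  nm <- registry$name
  with_preserved_seed(seed, {
    rf <- rlnorm(length(nm), meanlog = log(1000), sdlog = 0.5)
    rec <- runif(length(nm), 0.7, 1.0)
    mf <- tidyr::crossing(name = nm, matrix = names(matrix_base)) %>%
      mutate(matrix_factor = unname(matrix_base[.data$matrix]) *
               exp(rnorm(dplyr::n(), 0, matrix_spread_sdlog)))
  })
  names(rf) <- names(rec) <- nm
  if (!is.null(response_factor)) rf[names(response_factor)] <- response_factor
  if (!is.null(extraction_recovery)) rec[names(extraction_recovery)] <- extraction_recovery
  if (any(rf <= 0)) {
    abort("Response factors must be positive.", class = "residuval_validation_error")
  }
  if (any(rec <= 0 | rec > 1)) {
    abort("Extraction recoveries must lie in (0, 1].",
          class = "residuval_validation_error")
  }
  bl <- setNames(rep(0, length(nm)), nm)
  if (!is.null(blank_level)) bl[names(blank_level)] <- blank_level
  ir <- if (length(ion_ratio) == 1) setNames(rep(ion_ratio, length(nm)), nm) else ion_ratio

  mf <- bind_rows(mf, tibble(name = rep(nm, 1), matrix = "solvent", matrix_factor = 1))
  if (!is.null(matrix_factor)) {
    mf <- mf %>%
      anti_join(matrix_factor, by = c("name", "matrix")) %>%
      bind_rows(matrix_factor)
  }
  if (any(mf$matrix_factor <= 0)) {
    abort("Matrix factors must be positive.", class = "residuval_validation_error")
  }

  # enforce si sharing: every si analyte in a group and the group's IL-IS
  # carry identical matrix factors and extraction recovery
  assign_tbl <- ilis_assignment(registry)
  si_groups <- assign_tbl %>% filter(.data$si_ilis)
  for (g in unique(si_groups$ilis_group)) {
    members <- si_groups$compound[si_groups$ilis_group == g]
    ilis_name <- si_groups$ilis_name[si_groups$ilis_group == g][1]
    share <- c(members, ilis_name)
    rec[share] <- rec[members[1]]
    ref_mf <- mf %>% filter(.data$name == members[1]) %>%
      select("matrix", shared_mf = "matrix_factor")
    mf <- mf %>%
      left_join(ref_mf, by = "matrix") %>%
      mutate(matrix_factor = ifelse(.data$name %in% share,
                                    .data$shared_mf, .data$matrix_factor)) %>%
      select(-"shared_mf")
  }

  structure(
    list(
      compounds = tibble(name = nm, response_factor = unname(rf[nm]),
                         extraction_recovery = unname(rec[nm]),
                         blank_level = unname(bl[nm]),
                         ion_ratio = unname(ir[nm])),
      matrix_factors = mf,
      day_effect_sd = day_effect_sd,
      injection_cv = injection_cv,
      ion_ratio_cv = ion_ratio_cv,
      noise_floor = noise_floor,
      seed = seed
    ),
    class = "ground_truth"
  )
}

#' Simulate a validation dataset of peak areas
#'
#' Generates injections and sample metadata for the full validation design:
#' solvent and matrix-matched calibration series, fortified
#' precision/trueness samples, and procedural blanks. Quantifier areas
#' follow `response_factor * conc_extract * matrix_factor *
#' extraction_recovery * day_multiplier * exp(eps)` with lognormal
#' injection noise; qualifier areas are the quantifier times the compound's
#' fixed ion ratio with independent noise. Calibration standards are spiked
#' into the final extract and therefore bypass extraction recovery;
#' fortified, blank, and monitoring samples pass through it. IL-IS and TPP
#' areas are generated under the same model at their nominal levels (the
#' IL-IS experiences extraction losses in processed samples, TPP never
#' does).
#'
#' @param registry A compound registry.
#' @param design A [design_spec()].
#' @param truth A [ground_truth()] ledger covering every registry compound.
#' @param seed Seed for this realization; defaults to the ledger's seed.
#' @return A list with tibbles `injections` and `samples`.
#' @examples
#' reg <- soil_pesticide_registry()
#' sim <- simulate_dataset(reg, design_spec(), ground_truth(reg, seed = 7))
#' dplyr::count(sim$samples, role)
#' @export
simulate_dataset <- function(registry, design = design_spec(),
                             truth = ground_truth(registry), seed = truth$seed) {
  check_truth(registry, truth)
  cal <- tidyr::crossing(matrix = design$matrices,
                         nominal_conc = design$calibration_levels,
                         replicate = seq_len(design$cal_replicates)) %>%
    mutate(role = ifelse(.data$matrix == "solvent", "solvent_cal", "mm_cal"),
           day = 1L,
           sample_id = sprintf("cal_%s_L%g_r%d", .data$matrix,
                               .data$nominal_conc, .data$replicate))
  fort <- tidyr::crossing(nominal_conc = design$fortification_levels,
                          day = seq_len(design$days),
                          replicate = seq_len(design$replicates_per_level)) %>%
    mutate(matrix = design$validation_matrix, role = "fortified",
           sample_id = sprintf("fort_%s_L%g_d%d_r%d", .data$matrix,
                               .data$nominal_conc, .data$day, .data$replicate))
  blank <- tidyr::crossing(day = seq_len(design$days),
                           replicate = seq_len(design$blanks_per_day)) %>%
    mutate(matrix = design$validation_matrix, role = "blank", nominal_conc = 0,
           sample_id = sprintf("blank_%s_d%d_r%d", .data$matrix,
                               .data$day, .data$replicate))
  samples <- bind_rows(cal, fort, blank) %>%
    mutate(day = as.integer(.data$day), replicate = as.integer(.data$replicate)) %>%
    select("sample_id", "role", "matrix", "nominal_conc", "day", "replicate")

  injections <- with_preserved_seed(seed, {
    generate_areas(samples, registry, truth, design)
  })
  list(injections = injections, samples = validate_samples(samples))
}

#' Simulate a dilution series for LOQ determination
#'
#' Matrix-matched standards at the extended low-level series used to locate
#' the lowest level meeting the signal-to-noise identification criteria.
#'
#' @inheritParams simulate_dataset
#' @param matrix Soil matrix of the dilution series.
#' @return A list with tibbles `injections` and `samples`.
#' @export
simulate_dilution_series <- function(registry, design = design_spec(),
                                     truth = ground_truth(registry),
                                     matrix = design$validation_matrix,
                                     seed = truth$seed) {
  check_truth(registry, truth)
  samples <- tibble(nominal_conc = design$loq_levels) %>%
    mutate(matrix = matrix, role = "mm_cal", day = 1L, replicate = 1L,
           sample_id = sprintf("loq_%s_L%g", matrix, .data$nominal_conc)) %>%
    select("sample_id", "role", "matrix", "nominal_conc", "day", "replicate")
  injections <- with_preserved_seed(seed + 1L, {
    generate_areas(samples, registry, truth, design)
  })
  list(injections = injections, samples = samples)
}

#' Simulate a monitoring batch
#'
#' Each sample carries each analyte independently with probability
#' `prevalence`; detected residues draw their soil concentration from a
#' per-compound lognormal, non-detects sit at the compound's blank level.
#' Areas follow the same generative model as [simulate_dataset()] with
#' extraction recovery applied.
#'
#' @inheritParams simulate_dataset
#' @param n_samples Number of monitoring soil samples (>= 1).
#' @param prevalence Scalar or per-compound named vector in \[0, 1\].
#' @param conc_meanlog,conc_sdlog Lognormal parameters (scalar or named)
#'   of the residue concentration in ng/g for detected compounds.
#' @param matrix Soil matrix of the batch.
#' @return A list with tibbles `injections`, `samples`, and `truth_concs`
#'   (the latent true concentration of every sample-compound pair, for
#'   parameter-recovery tests).
#' @export
simulate_monitoring <- function(registry, truth = ground_truth(registry),
                                n_samples, prevalence,
                                conc_meanlog = log(20), conc_sdlog = 0.8,
                                matrix = "RFNc", design = design_spec(),
                                seed = truth$seed) {
  check_truth(registry, truth)
  if (n_samples < 1) {
    abort("`n_samples` must be >= 1.", class = "residuval_validation_error")
  }
  if (any(prevalence < 0 | prevalence > 1)) {
    abort("`prevalence` must lie in [0, 1].", class = "residuval_validation_error")
  }
  analytes <- registry$name[!registry$category %in%
                              c("internal_standard", "syringe_standard")]
  prev <- if (length(prevalence) == 1) {
    setNames(rep(prevalence, length(analytes)), analytes)
  } else prevalence
  ml <- if (length(conc_meanlog) == 1) {
    setNames(rep(conc_meanlog, length(analytes)), analytes)
  } else conc_meanlog
  sl <- if (length(conc_sdlog) == 1) {
    setNames(rep(conc_sdlog, length(analytes)), analytes)
  } else conc_sdlog

  samples <- tibble(
    sample_id = sprintf("mon_%03d", seq_len(n_samples)),
    role = "monitoring", matrix = matrix, nominal_conc = 0,
    day = 1L, replicate = seq_len(n_samples)
  )
  out <- with_preserved_seed(seed + 2L, {
    grid <- tidyr::crossing(sample_id = samples$sample_id, compound = analytes) %>%
      mutate(detect = rbinom(dplyr::n(), 1, prev[.data$compound]) == 1,
             true_conc = ifelse(.data$detect,
                                rlnorm(dplyr::n(), ml[.data$compound],
                                       sl[.data$compound]),
                                0))
    inj <- generate_areas(samples, registry, truth, design,
                          monitoring_concs = grid)
    list(injections = inj, truth_concs = grid)
  })
  list(injections = out$injections, samples = samples,
       truth_concs = out$truth_concs)
}

# core generative model; assumes RNG state already set by caller
generate_areas <- function(samples, registry, truth, design,
                           monitoring_concs = NULL) {
  sdlog <- sqrt(log(1 + truth$injection_cv^2))
  sdlog_ratio <- sqrt(log(1 + truth$ion_ratio_cv^2))
  n_days <- max(samples$day)
  day_mult <- exp(rnorm(n_days, 0, truth$day_effect_sd))

  grid <- tidyr::crossing(samples, name = registry$name) %>%
    left_join(select(registry, "name", "category", "expected_rt"), by = "name") %>%
    left_join(truth$compounds, by = "name") %>%
    left_join(truth$matrix_factors, by = c("name", "matrix"))
  if (any(is.na(grid$matrix_factor))) {
    missing <- grid %>% filter(is.na(.data$matrix_factor)) %>%
      distinct(.data$name, .data$matrix)
    abort(paste0("Ground truth lacks matrix factors for: ",
                 paste(paste(missing$name, missing$matrix, sep = "/"),
                       collapse = "; ")),
          class = "residuval_config_error")
  }

  is_standard <- grid$category %in% c("internal_standard", "syringe_standard")
  processed <- grid$role %in% c("fortified", "blank", "monitoring")

  # concentration of each compound in the injected extract (ng/mL; the
  # generator works at the reference 1 mL/g soil-to-extract policy)
  conc <- numeric(nrow(grid))
  analyte <- !is_standard
  conc[analyte & !processed] <- grid$nominal_conc[analyte & !processed]
  conc[analyte & processed] <-
    (grid$nominal_conc + grid$blank_level)[analyte & processed] *
    grid$extraction_recovery[analyte & processed]
  ilis <- grid$category == "internal_standard"
  conc[ilis & !processed] <- design$ilis_nominal
  conc[ilis & processed] <- design$ilis_nominal *
    grid$extraction_recovery[ilis & processed]
  tpp <- grid$category == "syringe_standard"
  conc[tpp] <- design$tpp_nominal

  if (!is.null(monitoring_concs)) {
    grid2 <- grid %>%
      left_join(monitoring_concs, by = c("sample_id", "name" = "compound"))
    mon <- grid2$role == "monitoring" & analyte
    conc[mon] <- (grid2$true_conc + grid2$blank_level)[mon] *
      grid2$extraction_recovery[mon]
  }

  quant_area <- grid$response_factor * conc * grid$matrix_factor *
    day_mult[grid$day] * exp(rnorm(nrow(grid), 0, sdlog))
  qual_area <- quant_area * grid$ion_ratio *
    exp(rnorm(nrow(grid), 0, sdlog_ratio))

  base <- grid %>%
    select("sample_id", compound = "name", rt = "expected_rt")
  bind_rows(
    base %>% mutate(transition_role = "quantifier", area = quant_area),
    base %>% mutate(transition_role = "qualifier", area = qual_area)
  ) %>%
    mutate(snr = .data$area / truth$noise_floor) %>%
    select("sample_id", "compound", "transition_role", "area", "rt", "snr") %>%
    arrange(.data$sample_id, .data$compound, .data$transition_role)
}

check_truth <- function(registry, truth) {
  if (!inherits(truth, "ground_truth")) {
    abort("`truth` must be a ground_truth object.",
          class = "residuval_config_error")
  }
  missing <- setdiff(registry$name, truth$compounds$name)
  if (length(missing) > 0) {
    abort(paste0("Ground truth lacks entries for: ",
                 paste(missing, collapse = ", ")),
          class = "residuval_config_error")
  }
  invisible(truth)
}

# run code under a seed without clobbering the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
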