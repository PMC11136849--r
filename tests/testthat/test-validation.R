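test_that("RSD: reference values, brute-force oracle, and guards", {
  expect_equal(rsd(c(10, 10, 10, 10)), 0)
  expect_equal(rsd(c(9, 10, 11)), 10)
  set.seed(31)
  for (i in 1:10) {
    v <- runif(sample(3:12, 1), 5, 50)
    # two-pass sample SD oracle
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1))
    expect_equal(rsd(v), 100 * s / m, tolerance = 1e-12)
  }
  expect_error(rsd(5), class = "residuval_insufficient_replicates_error")
  expect_error(rsd(c(-1, 1)), class = "residuval_undefined_rsd_error")
})

test_that("precision table: degenerate and noise-only cases", {
  conc <- tidyr::crossing(compound = c("a", "b"), nominal_conc = c(10, 25),
                          day = 1:3, replicate = 1:4) %>%
    dplyr::mutate(conc_ng_g = nominal_conc)
  out <- precision_table(conc)
  expect_equal(out$rsd_r, rep(0, 4))
  expect_equal(out$rsd_R, rep(0, 4))
  expect_equal(unique(out$n_pooled), 12L)
  expect_equal(unique(out$n_within_day), 4L)

  gap <- conc %>% dplyr::filter(!(day == 2 & replicate > 1))
  expect_error(precision_table(gap, repeatability_day = 2),
               class = "residuval_design_incompleteness_error")
  expect_error(precision_table(conc %>% dplyr::filter(day == 1)),
               class = "residuval_design_incompleteness_error")
})

test_that("without day effects RSDR tracks RSDr; day effects inflate RSDR", {
  reg <- toy_registry()
  nm <- reg$name
  base <- function(day_sd) {
    ground_truth(reg, seed = 17,
                 response_factor = stats::setNames(rep(1000, length(nm)), nm),
                 extraction_recovery = stats::setNames(rep(1, length(nm)), nm),
                 matrix_base = c(SR = 1.5, RFNo = 1.5, RFNc = 1.5,
                                 XFN = 1.5, DC = 1.5),
                 matrix_spread_sdlog = 0, injection_cv = 0.05,
                 day_effect_sd = day_sd)
  }
  run <- function(truth) {
    sim <- simulate_dataset(reg, toy_design(replicates_per_level = 4), truth)
    crv <- fit_curves(build_response_points(sim$injections, sim$samples, reg,
                                            "external"))
    conc <- quantify_samples(sim$injections, sim$samples, crv, reg,
                             mode = "external", roles = "fortified")
    precision_table(conc)
  }
  flat <- run(base(0))
  expect_lt(abs(mean(flat$rsd_R) - mean(flat$rsd_r)), 3)

  wobbly <- run(base(0.3))
  expect_gt(mean(wobbly$rsd_R), mean(wobbly$rsd_r))
})

test_that("relative recovery: formula and guards", {
  expect_equal(relative_recovery(10, 10), 100)
  expect_equal(relative_recovery(5.02, 10), 50.2)
  expect_error(relative_recovery(5, 0), class = "residuval_validation_error")
})

test_that("absolute recovery: ratio-of-ratios formula and pipeline recovery", {
  expect_equal(absolute_recovery(100, 200, 0.5), 100)
  expect_equal(absolute_recovery(50, 200, 0.5), 50)
  expect_error(absolute_recovery(1, 0, 0.5),
               class = "residuval_division_error")

  # an IL-IS with true extraction recovery 0.43 reads back as 43%
  reg <- toy_registry()
  truth <- noiseless_truth(reg, f = 1.7)
  truth$compounds$extraction_recovery[truth$compounds$name == "gamma-d3"] <- 0.43
  sim <- simulate_dataset(reg, toy_design(), truth)
  rec <- absolute_recoveries(sim$injections, sim$samples, reg)
  g <- rec %>% dplyr::filter(compound == "gamma-d3")
  expect_gt(nrow(g), 0)
  expect_equal(g$absolute_recovery_pct, rep(43, nrow(g)), tolerance = 1e-9)
  a <- rec %>% dplyr::filter(compound == "alpha-d5")
  expect_equal(a$absolute_recovery_pct, rep(100, nrow(a)), tolerance = 1e-9)
})

test_that("Horwitz precision function", {
  expect_equal(horwitz(1e-8)$rsd_bl, 32)   # 10 ng/g
  expect_equal(horwitz(1e-2)$rsd_bl, 4)
  C <- 10^runif(10, -9, -2)
  h <- horwitz(C)
  expect_equal(h$rsd_wl / h$rsd_bl, rep(2 / 3, 10))
  # halves for a 100-fold concentration increase
  expect_equal(horwitz(1e-6)$rsd_bl / horwitz(1e-4)$rsd_bl, 2)
  expect_true(all(diff(horwitz(sort(C))$rsd_bl) < 0))
  expect_error(horwitz(0), class = "residuval_domain_error")
  expect_equal(ng_g_to_mass_fraction(10), 1e-8)
})

test_that("LOQ: lowest level passing both strict S/N rules", {
  tbl <- tibble::tibble(compound = "a", level = c(0.1, 0.5, 1, 5),
                        snr_quant = c(3, 8, 12, 40),
                        snr_qual = c(1, 2, 5, 20))
  expect_equal(determine_loq(tbl)$loq_ng_g, 1)

  all_ok <- dplyr::mutate(tbl, snr_quant = 100, snr_qual = 100)
  expect_equal(determine_loq(all_ok)$loq_ng_g, 0.1)

  boundary <- dplyr::mutate(tbl, snr_quant = c(10, 10, 10, 10.5),
                            snr_qual = c(3, 3, 4, 4))
  expect_equal(determine_loq(boundary)$loq_ng_g, 5)

  none <- dplyr::mutate(tbl, snr_quant = 1)
  expect_error(determine_loq(none), class = "residuval_no_loq_error")
  expect_warning(out <- determine_loq(none, allow_missing = TRUE))
  expect_true(is.na(out$loq_ng_g))

  # ng/mL levels convert to ng/g through the units policy
  expect_equal(determine_loq(tbl, units_policy(2))$loq_ng_g, 2)
})

test_that("snr tables pivot dilution series injections per transition", {
  reg <- toy_registry()
  truth <- noiseless_truth(reg, f = 1)
  dil <- simulate_dilution_series(reg, design_spec(), truth, matrix = "SR")
  tbl <- snr_table(dil$injections, dil$samples, reg)
  expect_setequal(names(tbl), c("compound", "level", "snr_quant", "snr_qual"))
  expect_equal(nrow(tbl), 3 * 10)
  # noise-free S/N is area over the constant noise floor
  one <- tbl %>% dplyr::filter(compound == "alpha", level == 10)
  expect_equal(one$snr_quant, 1000 * 10 / truth$noise_floor)
})

test_that("validation report: flags, thresholds, and summary-row oracle", {
  tab <- load_table2_fixture()
  precision <- tab %>%
    dplyr::select(compound = analyte, dplyr::starts_with("rsdr_"),
                  dplyr::starts_with("rsdR_")) %>%
    tidyr::pivot_longer(-compound, names_to = c("kind", "nominal_conc"),
                        names_sep = "_", values_to = "value") %>%
    dplyr::mutate(nominal_conc = as.numeric(nominal_conc)) %>%
    tidyr::pivot_wider(names_from = kind, values_from = value) %>%
    dplyr::rename(rsd_r = rsdr, rsd_R = rsdR)
  recovery <- tab %>%
    dplyr::select(compound = analyte, dplyr::starts_with("rel_rec_")) %>%
    tidyr::pivot_longer(-compound, names_prefix = "rel_rec_",
                        names_to = "nominal_conc", values_to = "rel_rec_pct") %>%
    dplyr::mutate(nominal_conc = as.numeric(nominal_conc))
  loq <- tab %>% dplyr::select(compound = analyte, loq_ng_g)
  linearity <- tab %>% dplyr::select(compound = analyte, r_squared)

  report <- build_validation_report(precision, recovery, loq, linearity,
                                    soil_pesticide_registry())
  expect_equal(nrow(report), 38L)
  # bifenthrin: mean recovery 62% fails 70-120 but passes 60-140
  bif <- report[report$compound == "Bifenthrin", ]
  expect_false(bif$recovery_pass)
  expect_true(bif$recovery_extended_pass)
  expect_false(bif$rsdr_pass)  # 20.8 > 20 at the lowest level
  expect_true(all(report$linearity_pass))
  expect_true(all(report$loq_pass))

  # flags are monotone: tightening thresholds never flips fail -> pass
  tight <- build_validation_report(precision, recovery, loq, linearity,
                                   soil_pesticide_registry(),
                                   sante_thresholds(rsd_r_max = 10,
                                                    recovery_range = c(85, 110),
                                                    r_squared_min = 0.997,
                                                    loq_max = 5))
  for (fl in c("rsdr_pass", "recovery_pass", "linearity_pass", "loq_pass")) {
    expect_true(all(report[[fl]] | !tight[[fl]]))
  }

  smry <- summarize_validation_report(report)
  expect_equal(smry$rsdr_10[smry$statistic == "mean"], mean(tab$rsdr_10))
  expect_equal(smry$rel_rec_25[smry$statistic == "min"], min(tab$rel_rec_25))
  expect_equal(smry$rsdR_10[smry$statistic == "max"], max(tab$rsdR_10))
})
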