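test_that("selectivity: RT window and ion-ratio window boundaries", {
  expect_true(selectivity_check(7.4, 7.0, 2, 2)$rt_ok)
  expect_false(selectivity_check(7.6, 7.0, 2, 2)$rt_ok)
  expect_true(selectivity_check(7.5, 7.0, 2, 2)$rt_ok)  # inclusive at 0.5

  expect_true(selectivity_check(7, 7, 2.0, 2.0)$ion_ratio_ok)
  expect_true(selectivity_check(7, 7, 3.0, 2.0)$ion_ratio_ok)    # 1.5x
  expect_false(selectivity_check(7, 7, 3.02, 2.0)$ion_ratio_ok)  # 1.51x
  expect_true(selectivity_check(7, 7, 1.0, 2.0)$ion_ratio_ok)    # 0.5x
  expect_false(selectivity_check(7, 7, 0.99, 2.0)$ion_ratio_ok)
  # the stricter food/feed preset
  expect_false(selectivity_check(7, 7, 2.7, 2.0, ratio_tol = 30)$ion_ratio_ok)
  expect_error(selectivity_check(7, 7, NA, 2),
               class = "residuval_incomplete_identification_error")
})

test_that("specificity: blanks may reach but not exceed 30% of the LOQ", {
  expect_true(specificity_check(0, 5))
  expect_true(specificity_check(1.5, 5))    # exactly 0.3 x LOQ
  expect_false(specificity_check(1.55, 5))  # 0.31 x LOQ
  expect_error(specificity_check(1, 0), class = "residuval_validation_error")
})

test_that("blank-referenced reporting censors at the highest batch blank", {
  r <- blank_referenced_report(12, c(5, 6))
  expect_true(r$reported)
  r2 <- blank_referenced_report(5, c(5, 6))
  expect_false(r2$reported)
  expect_equal(r2$censor_reason, "not_above_blanks")
  # unflagged compounds bypass the rule entirely
  expect_true(blank_referenced_report(0.1, c(5, 6), flagged = FALSE)$reported)
  expect_error(blank_referenced_report(1, numeric(0)),
               class = "residuval_missing_blank_error")
})

test_that("exceedance: strict comparison and threshold monotonicity", {
  sums <- tibble::tibble(sample_id = c("a", "b"), residue_sum = c(50, 150))
  ex <- exceedance(sums, c(limit = 100))
  expect_equal(ex$n_exceeding, 1L)
  expect_equal(ex$fraction_exceeding, 0.5)
  at_limit <- tibble::tibble(sample_id = "a", residue_sum = 100)
  expect_equal(exceedance(at_limit, c(x = 100))$n_exceeding, 0L)

  both <- exceedance(sums)
  expect_gte(both$n_exceeding[both$limit == "netherlands"],
             both$n_exceeding[both$limit == "czech"])
  expect_error(exceedance(sums, c(bad = -1)),
               class = "residuval_validation_error")
})

test_that("noise-free monitoring screen reports spiked concentrations exactly", {
  reg <- toy_registry()
  truth <- noiseless_truth(reg, f = 1.4)
  des <- toy_design()
  sim <- simulate_dataset(reg, des, truth)
  crv <- fit_curves(build_response_points(sim$injections, sim$samples, reg,
                                          "internal"))
  mon <- simulate_monitoring(reg, truth, n_samples = 12, prevalence = 1,
                             conc_meanlog = log(60), conc_sdlog = 0.3,
                             matrix = "SR", design = des, seed = 90)
  # batch blanks come from the validation run
  all_inj <- dplyr::bind_rows(mon$injections, sim$injections %>%
    dplyr::semi_join(dplyr::filter(sim$samples, role == "blank"),
                     by = "sample_id"))
  all_smp <- dplyr::bind_rows(mon$samples,
                              dplyr::filter(sim$samples, role == "blank"))
  loq <- determine_loq(snr_table(
    simulate_dilution_series(reg, des, truth)$injections,
    simulate_dilution_series(reg, des, truth)$samples, reg))
  screened <- screen_samples(all_inj, all_smp, crv, reg, loq,
                             fallback_matrix = "SR",
                             cal_injections = sim$injections,
                             cal_samples = sim$samples)
  expect_true(all(screened$rt_ok))
  expect_true(all(screened$ion_ratio_ok))
  truthy <- screened %>%
    dplyr::inner_join(mon$truth_concs, by = c("sample_id", "compound"))
  above <- truthy %>% dplyr::filter(true_conc >= 2 * loq$loq_ng_g[1])
  expect_gt(nrow(above), 0)
  expect_equal(above$reported_conc, above$true_conc, tolerance = 1e-9)
})

test_that("censoring never increases occurrence statistics or residue sums", {
  reg <- toy_registry()
  truth <- noiseless_truth(reg, f = 1)
  truth$compounds$blank_level[truth$compounds$name == "gamma"] <- 8
  des <- toy_design()
  sim <- simulate_dataset(reg, des, truth)
  crv <- fit_curves(build_response_points(sim$injections, sim$samples, reg,
                                          "internal"))
  mon <- simulate_monitoring(reg, truth, n_samples = 30, prevalence = 0.6,
                             conc_meanlog = log(15), conc_sdlog = 0.6,
                             matrix = "SR", design = des, seed = 91)
  all_inj <- dplyr::bind_rows(mon$injections, sim$injections %>%
    dplyr::semi_join(dplyr::filter(sim$samples, role == "blank"),
                     by = "sample_id"))
  all_smp <- dplyr::bind_rows(mon$samples,
                              dplyr::filter(sim$samples, role == "blank"))
  dil <- simulate_dilution_series(reg, des, truth)
  loq <- determine_loq(snr_table(dil$injections, dil$samples, reg))

  open <- screen_samples(all_inj, all_smp, crv, reg, loq,
                         cal_injections = sim$injections,
                         cal_samples = sim$samples)
  censored <- screen_samples(all_inj, all_smp, crv, reg, loq,
                             blank_flagged = "gamma",
                             cal_injections = sim$injections,
                             cal_samples = sim$samples)
  occ_open <- summarize_occurrence(open)
  occ_cens <- summarize_occurrence(censored)
  cmp <- dplyr::inner_join(occ_open, occ_cens, by = "compound",
                           suffix = c("_open", "_cens"))
  expect_true(all(cmp$n_detects_cens <= cmp$n_detects_open))
  expect_true(all(is.na(cmp$max_conc_cens) |
                    cmp$max_conc_cens <= cmp$max_conc_open))
  sums <- dplyr::inner_join(residue_sums(open), residue_sums(censored),
                            by = "sample_id", suffix = c("_open", "_cens"))
  expect_true(all(sums$residue_sum_cens <= sums$residue_sum_open))
  for (th in c(20, 50, 100)) {
    expect_lte(exceedance(censored, c(x = th))$n_exceeding,
               exceedance(open, c(x = th))$n_exceeding)
  }
  # exceedance is monotone non-increasing in the threshold
  counts <- sapply(c(10, 30, 60, 120),
                   function(th) exceedance(open, c(x = th))$n_exceeding)
  expect_true(all(diff(counts) <= 0))
})

test_that("occurrence and batch statistics", {
  screened <- tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3"), each = 2),
    compound = rep(c("a", "b"), 3),
    conc_ng_g = c(10, 1, 20, 2, 30, 3),
    rt_ok = TRUE, ion_ratio_ok = TRUE, above_loq = TRUE, blank_ok = TRUE,
    reported_conc = c(10, NA, 20, NA, NA, 3)
  )
  occ <- summarize_occurrence(screened)
  a <- occ[occ$compound == "a", ]
  expect_equal(a$n_detects, 2L)
  expect_equal(a$detection_frequency, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(a$median_conc, 15)
  expect_equal(a$max_conc, 20)

  bs <- batch_stats(screened, k = 2)
  expect_equal(bs$frac_with_detect, 1)
  expect_equal(bs$frac_cooccurrence_k, 0)
  expect_error(summarize_occurrence(screened[0, ]),
               class = "residuval_empty_input_error")
})
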