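test_that("productivity costs follow the friction rules", {
  d <- 280
  # non-workers cost nothing regardless of reported loss
  expect_equal(productivity_cost(100, FALSE, "none", FALSE, d), 0)
  # long absence capped at the 60-working-day friction period
  expect_equal(productivity_cost(100, TRUE, "full", FALSE, d), 60 * d)
  expect_equal(productivity_cost(200, TRUE, "none", FALSE, d), 60 * d)
  # death before 65 also exhausts the friction period
  expect_equal(productivity_cost(5, TRUE, "none", TRUE, d), 60 * d)
  # partial returns
  expect_equal(productivity_cost(150, TRUE, "unpaid", FALSE, d), 30 * d)
  expect_equal(productivity_cost(150, TRUE, "reduced_hours", FALSE, d), 10 * d)
  expect_equal(productivity_cost(35, TRUE, "full", FALSE, d), 35 * d)
  expect_error(productivity_cost(-1, TRUE, "none", FALSE, d), "non-negative")
  # never exceeds the friction cap
  set.seed(1)
  days <- runif(200, 0, 400)
  costs <- productivity_cost(days, TRUE, sample(c("none", "full"), 200, TRUE),
                             runif(200) < 0.5, d)
  expect_true(all(costs <= 60 * d + 1e-9))
})

test_that("angiography cost is the DRG prorated by fluoroscopy minutes", {
  expect_equal(angiography_cost(0, 2320, 100), 0)
  expect_equal(angiography_cost(100, 2320, 100), 2320)
  expect_error(angiography_cost(10, 2320, 0), "positive")
  # published arm means reproduce the published cost pair within rounding
  expect_equal(round(angiography_cost(18.353, 2320, 100)), 426)
  expect_equal(round(angiography_cost(22.540, 2320, 100)), 523)
})

test_that("imputation applies the died-before-zero and conditional-mean rules", {
  coh <- toy_cohort(
    toy_patient(1, death_time = 10, ru_inpatient_days_6m = NA),   # -> 0
    toy_patient(2, ru_er_visits_6m = NA),                         # -> survivor mean
    toy_patient(3, ru_er_visits_6m = 1),
    toy_patient(4, ru_er_visits_6m = 0),
    toy_patient(5, ru_er_visits_6m = 0.2),
    toy_patient(6, death_time = 100, ru_inpatient_days_6m = NA)   # died during window
  )
  out <- suppressWarnings(impute_missing_hospital_use(coh))
  expect_equal(out$ru_inpatient_days_6m[1], 0)
  expect_equal(out$ru_er_visits_6m[2], mean(c(1, 0, 0.2)))
  log <- attr(out, "imputation_log")
  expect_true(nrow(log) >= 2)
  # lone patient in the died-during stratum falls back to the overall mean
  expect_warning(impute_missing_hospital_use(coh[c(1, 6), ]), "overall mean")
})

test_that("imputation is idempotent and preserves observed stratum means", {
  coh <- simulate_cohort(sim_config(n_per_arm = 2500, seed = 21))
  complete <- impute_missing_hospital_use(coh)
  attr(complete, "imputation_log") <- NULL
  expect_identical(as.data.frame(complete), as.data.frame(coh))

  blanked <- inject_missingness(coh, 0.2, seed = 7)
  imputed <- impute_missing_hospital_use(blanked)
  alive_6m <- is.na(coh$death_time) | coh$death_time > 182.5
  observed <- alive_6m & !is.na(blanked$ru_er_visits_6m)
  # imputed values equal the observed-stratum mean, so the stratum mean is unchanged
  expect_equal(mean(imputed$ru_er_visits_6m[alive_6m]),
               mean(blanked$ru_er_visits_6m[observed]), tolerance = 1e-12)
  # observed values untouched
  expect_equal(imputed$ru_er_visits_6m[observed],
               blanked$ru_er_visits_6m[observed])
})

test_that("per-patient totals apply the trial-specific costing rules", {
  uc <- default_unit_costs()
  unit <- function(cat) uc$unit_cost[uc$category == cat]
  coh <- toy_cohort(
    toy_patient(1),  # zero use, non-worker
    # dialysed but dead at day 100: therapy episodes costed, no dialysis-year
    toy_patient(2, renal_replacement = TRUE, rrt_day = 3, death_time = 100,
                ru_rrt_episodes = 2),
    # dialysed survivor: dialysis-year added
    toy_patient(3, renal_replacement = TRUE, rrt_day = 3, ru_rrt_episodes = 2),
    # 30-day self-reported inpatient days are excluded from the total
    toy_patient(4, ru_inpatient_days_30d = 10, ru_inpatient_days_6m = 2),
    toy_patient(5, ru_fluoro_minutes = 50)
  )
  bd <- patient_total_cost(coh, uc)
  expect_equal(bd$total[1], 0)
  expect_equal(bd$total[2], 2 * unit("rrt_episodes"))
  expect_equal(bd$total[3], 2 * unit("rrt_episodes") + unit("dialysis_year"))
  expect_equal(bd$total[4], 2 * unit("inpatient_days"))
  expect_equal(bd$total[5], angiography_cost(50, 2320, 100))
  # total equals the sum of the category columns
  cost_cols <- grep("^cost_", names(bd), value = TRUE)
  expect_equal(bd$total, rowSums(bd[cost_cols]), tolerance = 1e-6)

  bad <- dplyr::mutate(coh, ru_helicopter = 1)
  expect_error(patient_total_cost(bad, uc), "helicopter")
})

test_that("arm mean totals match the calibrated targets", {
  cfg <- sim_config(n_per_arm = 5000, seed = 17)
  coh <- simulate_cohort(cfg)
  bd <- patient_total_cost(coh)
  arm <- arm_cost_summary(bd)
  target <- expected_total_cost(cfg)
  expect_equal(unname(target),
               unname(c(25371, 24531)))  # calibration fixes the expectation
  for (a in c("CO-PCI", "MV-PCI")) {
    row <- arm[arm$arm == a, ]
    expect_lt(abs(row$mean_total - target[[a]]), 3 * row$se_total)
  }
  # arm mean equals the mean of per-patient totals (no double counting)
  expect_equal(arm$mean_total[arm$arm == "CO-PCI"],
               mean(bd$total[bd$arm == "CO-PCI"]))
})

test_that("outlier trimming removes exactly the values beyond the threshold", {
  coh <- simulate_cohort(sim_config(n_per_arm = 400, seed = 13))
  # no extreme values: identity under a generous threshold
  same <- trim_outliers(coh, list(method = "quantile", quantile = 1))
  expect_equal(nrow(attr(same, "trim_log")), 0)

  spiked <- coh
  big <- 100 * stats::quantile(coh$ru_icu_nights[coh$ru_icu_nights > 0], 0.99)
  spiked$ru_icu_nights[1] <- big
  out <- trim_outliers(spiked, list(method = "quantile", quantile = 0.999))
  expect_true(is.na(out$ru_icu_nights[1]))

  # removal count equals a brute-force scan with the same thresholds
  log <- attr(out, "trim_log")
  for (i in seq_len(nrow(log))) {
    f <- log$field[i]
    expect_equal(log$n_removed[i],
                 sum(spiked[[f]] > log$threshold[i], na.rm = TRUE))
  }
})
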