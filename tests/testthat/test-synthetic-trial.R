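test_that("identical seeds give byte-identical cohorts, different seeds differ", {
  a <- simulate_cohort(sim_config(n_per_arm = 60, seed = 123))
  b <- simulate_cohort(sim_config(n_per_arm = 60, seed = 123))
  attr(a, "sim_config") <- attr(b, "sim_config") <- NULL
  expect_identical(a, b)
  c_ <- simulate_cohort(sim_config(n_per_arm = 60, seed = 124))
  attr(c_, "sim_config") <- NULL
  expect_false(identical(a, c_))
})

test_that("a degenerate all-death arm has no follow-up activity", {
  cfg <- sim_config(n_per_arm = 80,
                    p_death_30d = c("CO-PCI" = 1, "MV-PCI" = 1), seed = 5)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$death_time <= 30))
  expect_true(all(is.na(coh$eq5d_30d)))
  expect_true(all(is.na(coh$eq5d_6m)))
  expect_true(all(is.na(coh$eq5d_12m)))
  expect_true(all(coh$ru_inpatient_days_6m == 0))
  expect_true(all(coh$ru_er_visits_12m == 0))
})

test_that("no patient carries post-death utilities or follow-up resource use", {
  coh <- simulate_cohort(sim_config(n_per_arm = 600, seed = 31))
  dead_30 <- !is.na(coh$death_time) & coh$death_time <= 30
  dead_6m <- !is.na(coh$death_time) & coh$death_time <= 182.5
  dead_1y <- !is.na(coh$death_time)
  expect_true(all(is.na(coh$eq5d_30d[dead_30])))
  expect_true(all(is.na(coh$eq5d_6m[dead_6m])))
  expect_true(all(is.na(coh$eq5d_12m[dead_1y])))
  expect_true(all(coh$ru_inpatient_days_6m[dead_6m] == 0))
  expect_true(all(coh$ru_er_visits_12m[dead_1y] == 0))
  expect_true(all(coh$eq5d_30d[!dead_30] >= -0.205 &
                    coh$eq5d_30d[!dead_30] <= 1, na.rm = TRUE))
})

test_that("state frequencies converge to the configured probabilities", {
  cfg <- sim_config(n_per_arm = 100000, seed = 77)
  coh <- classify_states(simulate_cohort(cfg))
  for (a in c("CO-PCI", "MV-PCI")) {
    n <- sum(coh$arm == a)
    p_cfg <- cfg$p_death_30d[[a]]
    p_hat <- mean(coh$state_30d[coh$arm == a] == "DEATH")
    se <- sqrt(p_cfg * (1 - p_cfg) / n)
    expect_lt(abs(p_hat - p_cfg), 3 * se)

    surv <- coh[coh$arm == a & coh$state_30d == "SURVIVOR", ]
    cp <- cfg$conditional_endpoint_probs
    state_of <- c(death = "DEATH", renal_failure = "RF", heart_failure = "HF",
                  mace = "MACE", as = "AS")
    for (e in cp$endpoint) {
      p <- cp[[a]][cp$endpoint == e]
      p_hat <- mean(surv$state_1y == state_of[[e]])
      se <- sqrt(p * (1 - p) / nrow(surv))
      expect_lt(abs(p_hat - p), 3 * se)
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_per_arm = 0), "at least 1")
  bad <- default_conditional_probs()
  bad$`CO-PCI`[1] <- bad$`CO-PCI`[1] + 0.1
  expect_error(sim_config(conditional_endpoint_probs = bad), "sum to 1")
  expect_error(sim_config(p_death_30d = c("CO-PCI" = 1.2, "MV-PCI" = 0.5)),
               "probability")
  expect_error(inject_missingness(toy_patient(), rate = 1.5), "probability")
})

test_that("missingness injection blanks eligible fields at the requested rate", {
  coh <- simulate_cohort(sim_config(n_per_arm = 2500, seed = 9))

  same <- inject_missingness(coh, 0)
  attr(same, "missingness_log") <- NULL
  expect_identical(as.data.frame(same), as.data.frame(coh))

  all_gone <- inject_missingness(coh, 1, seed = 1)
  alive_6m <- is.na(coh$death_time) | coh$death_time > 182.5
  expect_true(all(is.na(all_gone$eq5d_6m[alive_6m])))
  expect_true(all(is.na(all_gone$ru_er_visits_6m[alive_6m])))
  # post-death (structurally zero/absent) fields are untouched
  expect_true(all(all_gone$ru_inpatient_days_12m[!is.na(coh$death_time)] == 0))

  some <- inject_missingness(coh, 0.2, seed = 42)
  log <- attr(some, "missingness_log")
  n_elig <- sum(alive_6m)  # eligibility per 6m field
  frac <- sum(log$field == "eq5d_6m") / n_elig
  se <- sqrt(0.2 * 0.8 / n_elig)
  expect_lt(abs(frac - 0.2), 3 * se)
})

test_that("cohorts round-trip through CSV", {
  coh <- simulate_cohort(sim_config(n_per_arm = 25, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$mace_events, coh$mace_events)
  expect_equal(back$death_time, coh$death_time)
  expect_equal(back$ru_icu_nights, coh$ru_icu_nights, tolerance = 1e-12)
  expect_equal(as.character(back$arm), coh$arm)
})
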