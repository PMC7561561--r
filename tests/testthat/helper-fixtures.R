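# hand-built mini-cohorts and low-noise configs shared across tests

# one fully specified patient row; override any field
toy_patient <- function(id = 1, arm = "CO-PCI", ...) {
  row <- tibble::tibble(
    id = id, arm = arm,
    age_group = factor("50-75", c("<50", "50-75", ">75")),
    age_years = 62, male = TRUE, diabetes = FALSE,
    bmi_class = factor("overweight", c("normal_under", "overweight", "obese")),
    cvd_history = FALSE, risk_factor = TRUE,
    sim_endpoint = NA_character_,
    death_time = NA_real_, renal_replacement = FALSE, rrt_day = NA_real_,
    hf_time = NA_real_, mace_events = "",
    eq5d_30d = 0.75, eq5d_6m = 0.8, eq5d_12m = 0.82,
    worked_before = FALSE,
    return_to_work = factor("none", c("none", "unpaid", "reduced_hours", "full")),
    work_days_lost = 0,
    ru_pci = 0, ru_icu_nights = 0, ru_ward_nights = 0,
    ru_inpatient_days_30d = 0, ru_inpatient_days_6m = 0,
    ru_inpatient_days_12m = 0, ru_er_visits_6m = 0, ru_er_visits_12m = 0,
    ru_rrt_episodes = 0, ru_stents = 0, ru_fluoro_minutes = 0,
    ru_icd = 0, ru_ecmo = 0, ru_iabp = 0, ru_lvad = 0, ru_transplant = 0,
    ru_investigation = 0, ru_medication_days = 0
  )
  mods <- list(...)
  for (nm in names(mods)) row[[nm]] <- mods[[nm]]
  row
}

toy_cohort <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(rows)
}

# low-noise config for parameter-recovery checks: no utility covariate or
# wave effects, tight dispersion, so estimated coefficients sit close to
# the generating values
recovery_config <- function(n_per_arm, seed,
                            state_means = c(as = 0.773, hf = 0.773,
                                            mace = 0.773, rf = 0.773),
                            sd_between = 0.05, sd_within = 0.05) {
  zero_cov <- stats::setNames(rep(0, 8), names(default_utility_covariate_effects()))
  sim_config(
    n_per_arm = n_per_arm, seed = seed,
    utility_state_means = state_means,
    utility_wave_effects = c("30d" = 0, "6m" = 0, "12m" = 0),
    utility_covariate_effects = zero_cov,
    utility_sd_between = sd_between, utility_sd_within = sd_within
  )
}

# cohort of 30-day survivors with event times from a chosen family, for
# survival-fit recovery tests
survival_cohort <- function(n, seed, family = "weibull", shape = 1.5,
                            scale = 900, rate = NULL) {
  set.seed(seed)
  if (family == "weibull") {
    u <- stats::runif(n, stats::pweibull(30, shape, scale), 1)
    t <- stats::qweibull(u, shape, scale)
  } else {
    u <- stats::runif(n, stats::pexp(30, rate), 1)
    t <- stats::qexp(u, rate)
  }
  tibble::tibble(
    id = seq_len(n),
    arm = rep(c("CO-PCI", "MV-PCI"), length.out = n),
    age_group = factor(sample(c("<50", "50-75", ">75"), n, TRUE),
                       c("<50", "50-75", ">75")),
    male = stats::runif(n) < 0.7, diabetes = stats::runif(n) < 0.3,
    death_time = ifelse(t <= 365, t, NA_real_),
    renal_replacement = FALSE, rrt_day = NA_real_,
    hf_time = NA_real_, mace_events = ""
  )
}
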