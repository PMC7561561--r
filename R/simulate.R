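#' Configuration of the synthetic trial generator
#'
#' Assembles and validates the parameters of [simulate_cohort()]. The
#' defaults reproduce the published arm-level summaries of the two-arm
#' revascularisation trial the model is calibrated to: arm sizes 343,
#' 30-day mortality 43.3% / 51.5%, the conditional one-year endpoint
#' distribution among 30-day survivors, EQ5D panel means by health state
#' and follow-up wave, and heavily right-skewed resource-use costs whose
#' per-arm expected one-year totals equal `total_cost_targets`
#' (€25,371 / €24,531).
#'
#' Cost calibration works in two layers: per-category mean euro amounts
#' (`cost_means`) are drawn as gamma variables with coefficient of
#' variation `cost_cv`; the structural components (annual dialysis for
#' renal-failure survivors, friction-cost productivity losses) follow
#' their own rules. The gamma category means are then rescaled by a common
#' per-arm factor so that the analytic expected total
#' ([expected_total_cost()]) matches `total_cost_targets` exactly. Set
#' `total_cost_targets = NULL` to keep `cost_means` untouched.
#'
#' @param n_per_arm patients per arm.
#' @param p_death_30d named per-arm probability of death within 30 days.
#' @param conditional_endpoint_probs tibble with columns `endpoint`,
#'   `CO-PCI`, `MV-PCI`: distribution of the one-year endpoint
#'   (`death`, `renal_failure`, `heart_failure`, `mace`, `as`) conditional
#'   on 30-day survival; each arm must sum to 1.
#' @param utility_state_means mean EQ5D by one-year health state (reference
#'   covariate cell), applied at the 6- and 12-month waves.
#' @param utility_wave_effects additive shifts for the `30d`, `6m` and
#'   `12m` waves (the 30-day wave uses `as + wave effect` for everyone
#'   alive, before state-specific experience has accrued).
#' @param utility_covariate_effects named additive covariate shifts
#'   (`age_50_75`, `age_gt75`, `male`, `diabetes`, `bmi_overweight`,
#'   `bmi_obese`, `cvd_history`, `risk_factor`).
#' @param utility_sd_between,utility_sd_within between-patient
#'   (random-intercept) and residual standard deviations on the utility
#'   scale; draws are truncated to `utility_range`.
#' @param utility_range valid utility interval (German value-set floor).
#' @param cost_means tibble with columns `category`, `CO-PCI`, `MV-PCI`:
#'   mean euro cost per patient for each gamma-drawn resource category.
#' @param cost_cv coefficient of variation of the gamma cost draws.
#' @param cost_state_weights relative intensity of follow-up hospital /
#'   emergency-room use by one-year endpoint (`dying` applies to patients
#'   with a late death who are still alive at the wave). Renormalised
#'   within each wave so the configured arm means are preserved exactly;
#'   they induce the state gradient the cost panel model estimates.
#' @param total_cost_targets named per-arm expected one-year total cost the
#'   generator is rescaled to, or `NULL`.
#' @param covariate_prevalences named prevalences of `male`, `diabetes`,
#'   `cvd_history`, `risk_factor`.
#' @param bmi_probs probabilities of `normal_under`, `overweight`, `obese`.
#' @param age_group_weights probabilities of age groups `<50`, `50-75`,
#'   `>75`; ages are drawn uniformly within 30-49, 50-75, 76-95.
#' @param event_time_params per-event parametric family and parameters for
#'   event days inside (30, 365]; currently `exponential` (rate) and
#'   `weibull` (shape, scale) are understood.
#' @param mace_type_probs distribution of the MACE event type.
#' @param work_params friction-cost generator settings: probability that a
#'   patient aged under 65 worked before randomisation
#'   (`p_work_under65`), return-to-work distribution among surviving
#'   workers (`return_probs` over none/unpaid/reduced_hours/full), and the
#'   gamma mean/cv of days lost for full returners.
#' @param missingness_rate passed to [inject_missingness()] when positive.
#' @param seed integer RNG seed; identical seeds give byte-identical
#'   cohorts.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_per_arm = 343,
                       p_death_30d = c("CO-PCI" = 149 / 344, "MV-PCI" = 176 / 342),
                       conditional_endpoint_probs = default_conditional_probs(),
                       utility_state_means = c(as = 0.773, hf = 0.722,
                                               mace = 0.809, rf = 0.688),
                       utility_wave_effects = c("30d" = -0.031, "6m" = 0.045,
                                                "12m" = 0.060),
                       utility_covariate_effects = default_utility_covariate_effects(),
                       utility_sd_between = 0.12,
                       utility_sd_within = 0.08,
                       utility_range = c(UTILITY_FLOOR, 1),
                       cost_means = default_cost_means(),
                       cost_cv = 1.5,
                       cost_state_weights = c(as = 0.35, hf = 1.55, mace = 0.4,
                                              rf = 0.55, dying = 2),
                       total_cost_targets = c("CO-PCI" = 25371, "MV-PCI" = 24531),
                       covariate_prevalences = c(male = 0.76, diabetes = 0.32,
                                                 cvd_history = 0.30,
                                                 risk_factor = 0.70),
                       bmi_probs = c(normal_under = 0.35, overweight = 0.45,
                                     obese = 0.20),
                       age_group_weights = c("<50" = 33 / 686, "50-75" = 439 / 686,
                                             ">75" = 214 / 686),
                       event_time_params = list(
                         death = list(family = "exponential", rate = 1 / 150),
                         heart_failure = list(family = "exponential", rate = 1 / 150),
                         mace = list(family = "exponential", rate = 1 / 120)
                       ),
                       mace_type_probs = c(MI = 0.15, stroke = 0.10,
                                           urgent_revasc = 0.25,
                                           staged_revasc = 0.50),
                       work_params = list(p_work_under65 = 0.80,
                                          return_probs = c(none = 0.30,
                                                           unpaid = 0.15,
                                                           reduced_hours = 0.15,
                                                           full = 0.40),
                                          days_lost_mean = 35,
                                          days_lost_cv = 0.5),
                       missingness_rate = 0,
                       seed = NULL) {
  if (!is.numeric(n_per_arm) || n_per_arm < 1) {
    stop_config("`n_per_arm` must be at least 1")
  }
  assert_prob(p_death_30d, "p_death_30d")
  stopifnot(all(.arms %in% names(p_death_30d)))
  cp <- conditional_endpoint_probs
  stopifnot(is.data.frame(cp), all(c("endpoint", .arms) %in% names(cp)),
            setequal(cp$endpoint, .endpoints))
  for (a in .arms) assert_prob_vector(cp[[a]], paste0("conditional_endpoint_probs$`", a, "`"))
  assert_prob_vector(age_group_weights, "age_group_weights")
  assert_prob_vector(bmi_probs, "bmi_probs")
  assert_prob_vector(work_params$return_probs, "work_params$return_probs")
  assert_prob(covariate_prevalences, "covariate_prevalences")
  assert_prob(missingness_rate, "missingness_rate")
  assert_prob(mace_type_probs, "mace_type_probs")
  if (any(cost_means[[2]] < 0) || any(cost_means[[3]] < 0)) {
    stop_config("cost means must be non-negative")
  }
  if (utility_range[1] < UTILITY_FLOOR - 1e-9 || utility_range[2] > 1) {
    stop_config("utility_range must lie within [%.3f, 1]", UTILITY_FLOOR)
  }
  cfg <- list(
    n_per_arm = as.integer(n_per_arm), p_death_30d = p_death_30d,
    conditional_endpoint_probs = cp,
    utility_state_means = utility_state_means,
    utility_wave_effects = utility_wave_effects,
    utility_covariate_effects = utility_covariate_effects,
    utility_sd_between = utility_sd_between,
    utility_sd_within = utility_sd_within,
    utility_range = utility_range,
    cost_means = cost_means, cost_cv = cost_cv,
    cost_state_weights = cost_state_weights,
    total_cost_targets = total_cost_targets,
    covariate_prevalences = covariate_prevalences,
    bmi_probs = bmi_probs, age_group_weights = age_group_weights,
    event_time_params = event_time_params,
    mace_type_probs = mace_type_probs,
    work_params = work_params,
    missingness_rate = missingness_rate, seed = seed,
    unit_costs = default_unit_costs()
  )
  class(cfg) <- "sim_config"
  cfg$cost_means <- rescale_cost_means(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_conditional_probs <- function() {
  cnt <- ref_tree_counts()
  tibble::tibble(
    endpoint = .endpoints,
    `CO-PCI` = cnt$conditional$`CO-PCI` / cnt$survivors_30d[["CO-PCI"]],
    `MV-PCI` = cnt$conditional$`MV-PCI` / cnt$survivors_30d[["MV-PCI"]]
  )
}

#' @rdname sim_config
#' @export
default_utility_covariate_effects <- function() {
  u <- ref_utility_model()
  stats::setNames(u$estimate[-(1:4)], u$term[-(1:4)])
}

# gamma-drawn cost categories: published category means, with the
# follow-up-reported ones split across the 6- and 12-month waves and a
# nominal 30-day self-reported inpatient mean (excluded from totals by the
# costing rules but needed by the imputation machinery)
#' @rdname sim_config
#' @export
default_cost_means <- function() {
  tibble::tribble(
    ~category,               ~`CO-PCI`, ~`MV-PCI`,
    "pci",                        1052,       302,
    "icu_nights",                 7527,      7229,
    "ward_nights",                1500,      1664,
    "inpatient_days_30d",          400,       700,
    "inpatient_days_6m",           306,       537,
    "inpatient_days_12m",          305,       537,
    "er_visits_6m",                 75,        51,
    "er_visits_12m",                74,        50,
    "rrt_episodes",                 92,       135,
    "stents",                      185,       246,
    "fluoro_minutes",              426,       523,
    "icd",                         113,       121,
    "ecmo",                        600,       984,
    "iabp",                        115,       102,
    "lvad",                       6046,      5074,
    "transplant",                   62,         0,
    "investigation",                 2,         2,
    "medication_days",             340,       363
  )
}

# survival probabilities at the follow-up waves implied by a config
config_survival <- function(cfg) {
  q_death <- vapply(.arms, function(a) {
    cp <- cfg$conditional_endpoint_probs
    cp[[a]][cp$endpoint == "death"]
  }, numeric(1))
  etp <- cfg$event_time_params$death
  f_half <- trunc_event_cdf(etp, 182.5)
  p30 <- 1 - cfg$p_death_30d[.arms]
  tibble::tibble(
    arm = .arms,
    alive_30d = unname(p30),
    alive_6m = unname(p30 * (1 - q_death * f_half)),
    alive_12m = unname(p30 * (1 - q_death))
  )
}

# cdf at `t` of an event-time family restricted to (30, 365]
trunc_event_cdf <- function(par, t) {
  pfun <- switch(par$family,
    exponential = function(x) stats::pexp(x, par$rate),
    weibull = function(x) stats::pweibull(x, par$shape, par$scale),
    stop_config("unsupported event-time family '%s'", par$family)
  )
  (pfun(t) - pfun(30)) / (pfun(365) - pfun(30))
}

# per-element draw of an event day inside (30, hi)
trunc_event_draw_before <- function(hi, par) {
  pfun <- switch(par$family,
    exponential = function(x) stats::pexp(x, par$rate),
    weibull = function(x) stats::pweibull(x, par$shape, par$scale),
    stop_config("unsupported event-time family '%s'", par$family)
  )
  qfun <- switch(par$family,
    exponential = function(p) stats::qexp(p, par$rate),
    weibull = function(p) stats::qweibull(p, par$shape, par$scale)
  )
  qfun(stats::runif(length(hi), pfun(30), pfun(hi)))
}

trunc_event_draw <- function(n, par) {
  qfun <- switch(par$family,
    exponential = function(p) stats::qexp(p, par$rate),
    weibull = function(p) stats::qweibull(p, par$shape, par$scale),
    stop_config("unsupported event-time family '%s'", par$family)
  )
  pfun <- switch(par$family,
    exponential = function(x) stats::pexp(x, par$rate),
    weibull = function(x) stats::pweibull(x, par$shape, par$scale)
  )
  qfun(stats::runif(n, pfun(30), pfun(365)))
}

#' Analytic expected one-year total cost under a simulation config
#'
#' Closed-form expectation of the per-patient one-year total cost produced
#' by [simulate_cohort()] followed by [patient_total_cost()], by arm. Used
#' to rescale the generator to its calibration targets and as the
#' construction oracle in tests: gamma categories contribute their means
#' (30-day self-reported inpatient days are excluded by the costing rules),
#' annual dialysis contributes `P(renal failure) x unit cost`, and
#' productivity contributes the friction-rule expectation over the
#' work-status and survival distribution.
#'
#' @param config a [sim_config()].
#' @return named numeric, expected total euro cost per arm.
#' @export
expected_total_cost <- function(config) {
  vapply(.arms, function(a) expected_arm_cost(config, a), numeric(1))
}

expected_arm_cost <- function(cfg, arm) {
  cm <- cfg$cost_means
  gamma_part <- sum(cm[[arm]][cm$category != "inpatient_days_30d"])
  gamma_part + structural_arm_cost(cfg, arm)
}

structural_arm_cost <- function(cfg, arm) {
  uc <- cfg$unit_costs
  unit <- function(cat) uc$unit_cost[uc$category == cat]
  cp <- cfg$conditional_endpoint_probs
  q <- stats::setNames(cp[[arm]], cp$endpoint)
  p30 <- cfg$p_death_30d[[arm]]
  p_rf <- (1 - p30) * q[["renal_failure"]]
  dialysis <- p_rf * unit("dialysis_year")

  w <- cfg$age_group_weights
  p_under65 <- w[["<50"]] + w[["50-75"]] * (65 - 50) / (75 - 50)
  p_work <- p_under65 * cfg$work_params$p_work_under65
  p_die_1y <- p30 + (1 - p30) * q[["death"]]
  rp <- cfg$work_params$return_probs
  e_full <- egamma_capped(cfg$work_params$days_lost_mean,
                          cfg$work_params$days_lost_cv, 60)
  e_days <- p_die_1y * 60 +
    (1 - p_die_1y) * (rp[["none"]] * 60 + rp[["unpaid"]] * 30 +
                        rp[["reduced_hours"]] * 10 + rp[["full"]] * e_full)
  productivity <- p_work * e_days * unit("work_day")
  unname(dialysis + productivity)
}

# rescale gamma category means so the analytic expected total equals the
# configured per-arm targets
rescale_cost_means <- function(cfg) {
  cm <- cfg$cost_means
  if (is.null(cfg$total_cost_targets)) return(cm)
  for (a in .arms) {
    counted <- cm$category != "inpatient_days_30d"
    structural <- structural_arm_cost(cfg, a)
    target <- cfg$total_cost_targets[[a]]
    gamma_sum <- sum(cm[[a]][counted])
    scale <- (target - structural) / gamma_sum
    if (scale <= 0) stop_config("total_cost_targets below structural costs for %s", a)
    cm[[a]][counted] <- cm[[a]][counted] * scale
  }
  cm
}

#' Generate a synthetic patient-level trial cohort
#'
#' Draws `2 * n_per_arm` patients with the statistical structure the
#' downstream analysis assumes: per-arm Bernoulli 30-day mortality, a
#' mutually exclusive one-year endpoint for each 30-day survivor, event
#' days inside (30, 365] from the configured parametric families, EQ5D
#' panels generated as patient random intercept + state/wave/covariate
#' shifts + residual noise truncated to the valid utility range, and
#' right-skewed gamma resource-use quantities. Follow-up fields are
#' structurally absent after death.
#'
#' @param config a [sim_config()].
#' @return tibble, one row per patient, with a `sim_config` attribute. The
#'   `sim_endpoint` column records the generator's true endpoint for
#'   recovery tests; `death_time` is `NA` for patients alive at day 365;
#'   `mace_events` serialises events as semicolon-joined `type:day` tokens;
#'   resource quantities live in `ru_*` columns in the units of
#'   [default_unit_costs()].
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cohort <- dplyr::bind_rows(lapply(.arms, function(a) simulate_arm(config, a)))
  cohort$id <- seq_len(nrow(cohort))
  cohort <- dplyr::relocate(cohort, "id")
  if (config$missingness_rate > 0) {
    cohort <- inject_missingness(cohort, config$missingness_rate)
  }
  attr(cohort, "sim_config") <- config
  cohort
}

simulate_arm <- function(cfg, arm) {
  n <- cfg$n_per_arm
  prev <- cfg$covariate_prevalences
  age_group <- sample(names(cfg$age_group_weights), n, TRUE,
                      prob = cfg$age_group_weights)
  age_lo <- c("<50" = 30, "50-75" = 50, ">75" = 76)[age_group]
  age_hi <- c("<50" = 49, "50-75" = 75, ">75" = 95)[age_group]
  age_years <- stats::runif(n, age_lo, age_hi)
  pat <- tibble::tibble(
    arm = arm,
    age_group = factor(age_group, levels = names(cfg$age_group_weights)),
    age_years = age_years,
    male = stats::runif(n) < prev[["male"]],
    diabetes = stats::runif(n) < prev[["diabetes"]],
    bmi_class = factor(sample(names(cfg$bmi_probs), n, TRUE, cfg$bmi_probs),
                       levels = names(cfg$bmi_probs)),
    cvd_history = stats::runif(n) < prev[["cvd_history"]],
    risk_factor = stats::runif(n) < prev[["risk_factor"]]
  )

  # events -----------------------------------------------------------------
  died_30d <- stats::runif(n) < cfg$p_death_30d[[arm]]
  cp <- cfg$conditional_endpoint_probs
  endpoint <- rep(NA_character_, n)
  endpoint[!died_30d] <- sample(cp$endpoint, sum(!died_30d), TRUE,
                                prob = cp[[arm]])
  endpoint[died_30d] <- "death_30d"
  pat$sim_endpoint <- endpoint

  death_time <- rep(NA_real_, n)
  death_time[died_30d] <- stats::runif(sum(died_30d), 0.5, 30)
  late_death <- endpoint == "death"
  death_time[late_death] <- trunc_event_draw(sum(late_death),
                                             cfg$event_time_params$death)
  pat$death_time <- death_time

  # patients dying between 30 days and one year carry the morbidity burden
  # they held before death: a pre-death state drawn from the arm's
  # non-death endpoint mix, with the triggering event placed before the
  # death day. This makes the conditional (state-given) long-term death
  # hazard equal across arms, the pattern the trial's survival analysis
  # estimated; it also exercises the classification priority (a dialysed
  # or re-hospitalised patient who dies is still DEATH).
  q_end <- stats::setNames(cp[[arm]], cp$endpoint)
  pre_state <- rep(NA_character_, n)
  if (any(late_death <- endpoint == "death")) {
    ev <- c("as", "renal_failure", "heart_failure", "mace")
    pre_state[late_death] <- sample(ev, sum(late_death), TRUE,
                                    prob = q_end[ev])
  }

  rrt <- endpoint == "renal_failure" |
    (!is.na(pre_state) & pre_state == "renal_failure")
  pat$renal_replacement <- rrt
  pat$rrt_day <- ifelse(rrt, ceiling(stats::runif(n, 0, 19)), NA_real_)

  hf <- endpoint == "heart_failure"
  hf_dec <- !is.na(pre_state) & pre_state == "heart_failure"
  pat$hf_time <- rep(NA_real_, n)
  pat$hf_time[hf] <- trunc_event_draw(sum(hf), cfg$event_time_params$heart_failure)
  pat$hf_time[hf_dec] <- trunc_event_draw_before(
    death_time[hf_dec], cfg$event_time_params$heart_failure)

  mace <- endpoint == "mace"
  mace_dec <- !is.na(pre_state) & pre_state == "mace"
  pat$mace_events <- rep("", n)
  if (any(mace)) {
    day <- round(trunc_event_draw(sum(mace), cfg$event_time_params$mace))
    type <- sample(names(cfg$mace_type_probs), sum(mace), TRUE,
                   cfg$mace_type_probs)
    pat$mace_events[mace] <- paste0(type, ":", day)
  }
  if (any(mace_dec)) {
    day <- round(trunc_event_draw_before(death_time[mace_dec],
                                         cfg$event_time_params$mace))
    type <- sample(names(cfg$mace_type_probs), sum(mace_dec), TRUE,
                   cfg$mace_type_probs)
    pat$mace_events[mace_dec] <- paste0(type, ":", day)
  }

  # utilities ---------------------------------------------------------------
  covshift <- utility_covariate_shift(pat, cfg$utility_covariate_effects)
  b_i <- stats::rnorm(n, 0, cfg$utility_sd_between)
  state6 <- endpoint_to_state(endpoint)
  sm <- cfg$utility_state_means
  wv <- cfg$utility_wave_effects
  lp <- list(
    eq5d_30d = sm[["as"]] + wv[["30d"]] + covshift,
    eq5d_6m = sm[tolower(state6)] + wv[["6m"]] + covshift,
    eq5d_12m = sm[tolower(state6)] + wv[["12m"]] + covshift
  )
  alive_at <- list(
    eq5d_30d = is.na(death_time) | death_time > 30,
    eq5d_6m = is.na(death_time) | death_time > 182.5,
    eq5d_12m = is.na(death_time)
  )
  for (w in names(lp)) {
    u <- lp[[w]] + b_i + stats::rnorm(n, 0, cfg$utility_sd_within)
    u <- pmin(pmax(u, cfg$utility_range[1]), cfg$utility_range[2])
    u[!alive_at[[w]]] <- NA_real_
    pat[[w]] <- unname(u)
  }

  # work and productivity inputs -------------------------------------------
  wp <- cfg$work_params
  pat$worked_before <- pat$age_years < 65 & stats::runif(n) < wp$p_work_under65
  died_1y <- !is.na(death_time)
  ret <- rep("none", n)
  surv_worker <- pat$worked_before & !died_1y
  ret[surv_worker] <- sample(names(wp$return_probs), sum(surv_worker), TRUE,
                             wp$return_probs)
  pat$return_to_work <- factor(ret, levels = c("none", "unpaid",
                                               "reduced_hours", "full"))
  days <- rep(0, n)
  days[pat$worked_before & died_1y] <- 365
  days[surv_worker] <- dplyr::case_when(
    ret[surv_worker] == "none" ~ 200,
    ret[surv_worker] == "unpaid" ~ 150,
    ret[surv_worker] == "reduced_hours" ~ 100,
    TRUE ~ rgamma_mean_cv(sum(surv_worker), wp$days_lost_mean, wp$days_lost_cv)
  )
  pat$work_days_lost <- days

  # resource use ------------------------------------------------------------
  surv <- config_survival(cfg)
  surv <- surv[surv$arm == arm, ]
  eligibility <- list(inpatient_days_30d = list(p = surv$alive_30d, ok = alive_at$eq5d_30d),
                      inpatient_days_6m = list(p = surv$alive_6m, ok = alive_at$eq5d_6m),
                      inpatient_days_12m = list(p = surv$alive_12m, ok = alive_at$eq5d_12m),
                      er_visits_6m = list(p = surv$alive_6m, ok = alive_at$eq5d_6m),
                      er_visits_12m = list(p = surv$alive_12m, ok = alive_at$eq5d_12m))
  uc <- cfg$unit_costs
  # follow-up hospital use is concentrated in the sicker endpoint states;
  # weights are renormalised per wave so arm means stay exact
  sw <- cfg$cost_state_weights
  w_pat <- unname(sw[c(as = "as", renal_failure = "rf", heart_failure = "hf",
                       mace = "mace", death = "dying",
                       death_30d = "dying")[endpoint]])
  q_end <- stats::setNames(cp[[arm]], cp$endpoint)
  f_half <- trunc_event_cdf(cfg$event_time_params$death, 182.5)
  ew <- function(p_dying_alive) {
    probs <- c(q_end[c("as", "renal_failure", "heart_failure", "mace")],
               dying = unname(q_end[["death"]] * p_dying_alive))
    probs <- probs / sum(probs)
    sum(probs * sw[c("as", "rf", "hf", "mace", "dying")])
  }
  ew_wave <- c(inpatient_days_30d = ew(1), inpatient_days_6m = ew(1 - f_half),
               inpatient_days_12m = ew(0), er_visits_6m = ew(1 - f_half),
               er_visits_12m = ew(0))
  for (k in seq_len(nrow(cfg$cost_means))) {
    cat <- cfg$cost_means$category[k]
    mean_cost <- cfg$cost_means[[arm]][k]
    unit <- uc$unit_cost[uc$category == base_category(cat)]
    q <- numeric(n)
    if (cat %in% names(eligibility)) {
      el <- eligibility[[cat]]
      m_i <- (mean_cost / unit / el$p) * w_pat[el$ok] / ew_wave[[cat]]
      q[el$ok] <- rgamma_mean_cv(sum(el$ok), m_i, cfg$cost_cv)
    } else {
      q <- rgamma_mean_cv(n, mean_cost / unit, cfg$cost_cv)
    }
    pat[[paste0("ru_", cat)]] <- q
  }
  pat
}

utility_covariate_shift <- function(pat, eff) {
  eff[["age_50_75"]] * (pat$age_group == "50-75") +
    eff[["age_gt75"]] * (pat$age_group == ">75") +
    eff[["male"]] * pat$male +
    eff[["diabetes"]] * pat$diabetes +
    eff[["bmi_overweight"]] * (pat$bmi_class == "overweight") +
    eff[["bmi_obese"]] * (pat$bmi_class == "obese") +
    eff[["cvd_history"]] * pat$cvd_history +
    eff[["risk_factor"]] * pat$risk_factor
}

endpoint_to_state <- function(endpoint) {
  out <- dplyr::case_when(
    endpoint == "renal_failure" ~ "RF",
    endpoint == "heart_failure" ~ "HF",
    endpoint == "mace" ~ "MACE",
    TRUE ~ "AS"
  )
  out
}

# resource column -> unit-cost category (wave suffixes share a tariff)
base_category <- function(cat) {
  sub("_(30d|6m|12m)$", "", cat)
}

#' Blank follow-up fields completely at random
#'
#' Marks follow-up EQ5D utilities and self-reported hospitalisation /
#' emergency-room quantities missing with probability `rate` among records
#' that are structurally present (the patient was alive at the follow-up);
#' post-death fields are never touched. The blanked cells are recorded in
#' the `missingness_log` attribute for test assertions and imputation
#' checks.
#'
#' @param cohort a cohort tibble from [simulate_cohort()].
#' @param rate probability each eligible field is blanked.
#' @param seed optional RNG seed.
#' @return the cohort with `NA`s injected, carrying a `missingness_log`
#'   attribute (tibble with columns `id`, `field`).
#' @export
inject_missingness <- function(cohort, rate, seed = NULL) {
  assert_prob(rate, "rate")
  if (!is.null(seed)) set.seed(seed)
  waves <- list(
    "30d" = list(fields = c("eq5d_30d", "ru_inpatient_days_30d"), tmin = 30),
    "6m" = list(fields = c("eq5d_6m", "ru_inpatient_days_6m", "ru_er_visits_6m"),
                tmin = 182.5),
    "12m" = list(fields = c("eq5d_12m", "ru_inpatient_days_12m", "ru_er_visits_12m"),
                 tmin = 365)
  )
  log <- list()
  for (w in waves) {
    alive <- is.na(cohort$death_time) | cohort$death_time > w$tmin
    for (f in intersect(w$fields, names(cohort))) {
      hit <- alive & stats::runif(nrow(cohort)) < rate
      if (any(hit)) {
        cohort[[f]][hit] <- NA_real_
        log[[length(log) + 1]] <- tibble::tibble(id = cohort$id[hit], field = f)
      }
    }
  }
  attr(cohort, "missingness_log") <-
    if (length(log)) dplyr::bind_rows(log) else tibble::tibble(id = integer(), field = character())
  cohort
}
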