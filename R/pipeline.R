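#' Run the full cost-utility pipeline on a patient-level cohort
#'
#' Chains every estimation and modelling stage: health-state
#' classification, outlier screening and conditional-mean imputation,
#' within-trial costing, decision-tree probabilities with relative risks,
#' parametric survival fits for the long-term death / heart-failure / MACE
#' transitions, random-effect utility and cost panel models, and the three
#' economic evaluations -- the 30-day cost-effectiveness analysis
#' (composite death / renal-failure outcome), the within-trial one-year
#' cost-utility analysis and the lifelong decision-tree + Markov
#' cost-utility analysis.
#'
#' @param cohort patient-level cohort tibble (see [simulate_cohort()] for
#'   the expected columns).
#' @param unit_costs unit-cost table.
#' @param life_table life table (`age`, `annual_death_prob`).
#' @param discount annual discount rate applied beyond year one.
#' @param horizon_age Markov horizon age.
#' @param families candidate survival families passed to [fit_survival()].
#' @param trim optional outlier rule passed to [trim_outliers()]; `NULL`
#'   skips screening.
#' @param drg_cost,reference_minutes angiography DRG proration.
#' @return object of class `cua_pipeline`: all fitted components plus
#'   `$results`, a list of `ce_result` tibbles (`cea_30d`, `cua_1y`,
#'   `cua_lifelong`), and `$icers`, the incremental summary across the
#'   three analyses.
#' @export
cua_pipeline <- function(cohort,
                         unit_costs = default_unit_costs(),
                         life_table = synthetic_life_table(),
                         discount = 0.03, horizon_age = 100,
                         families = c("exponential", "weibull", "gompertz",
                                      "loglogistic", "lognormal"),
                         trim = list(method = "quantile", quantile = 0.999),
                         drg_cost = 2320, reference_minutes = 100) {
  cohort <- classify_states(cohort)
  if (!is.null(trim)) {
    imputable <- intersect(unlist(purrr::map(.fu_waves, "fields")),
                           names(cohort))
    cohort <- trim_outliers(cohort, trim, fields = imputable)
  }
  cohort <- impute_missing_hospital_use(cohort)
  breakdown <- patient_total_cost(cohort, unit_costs, drg_cost,
                                  reference_minutes)
  arm_costs <- arm_cost_summary(breakdown)
  year1_costs <- stats::setNames(arm_costs$mean_total, arm_costs$arm)[.arms]

  tree <- estimate_tree_probabilities(cohort)
  utility_model <- fit_panel_model(cohort, "utility")
  utility_model_lt <- fit_panel_model(cohort, "utility", mace_longterm = TRUE)
  cost_model <- fit_panel_model(cohort, "cost", unit_costs = unit_costs)

  death_fit <- fit_survival(cohort, "death", families)
  hf_fit <- fit_survival(cohort, "heart_failure", families)
  mace_fit <- fit_survival(cohort, "mace", families)

  u30 <- c(mean(cohort$eq5d_30d[cohort$arm == "CO-PCI"], na.rm = TRUE),
           mean(cohort$eq5d_30d[cohort$arm == "MV-PCI"], na.rm = TRUE))
  names(u30) <- .arms
  utilities <- list(u30 = u30,
                    state = state_values_marginal(utility_model, cohort))
  markov <- list(
    death_fit = death_fit, hf_fit = hf_fit, mace_fit = mace_fit,
    life_table = life_table,
    utilities = state_values_marginal(utility_model_lt, cohort),
    # panel cost response covers a six-month recall window
    costs_monthly = state_values_marginal(cost_model, cohort) / 6,
    p_rf = 0
  )
  mix <- covariate_mix(cohort)

  year1 <- run_decision_tree(tree, utilities, year1_costs)
  lifelong <- lifelong_evaluation(tree, utilities, year1_costs, markov, mix,
                                  discount, horizon_age)
  cea <- dplyr::transmute(year1, arm = .data$arm, cost = .data$cost,
                          effect = 1 - .data$p_death_rf_30d)
  cua_1y <- dplyr::transmute(year1, arm = .data$arm, cost = .data$cost,
                             effect = .data$qaly)
  cua_ll <- dplyr::transmute(lifelong, arm = .data$arm, cost = .data$cost,
                             effect = .data$qaly)
  results <- list(cea_30d = cea, cua_1y = cua_1y, cua_lifelong = cua_ll)
  icers <- purrr::imap(results, function(res, nm) {
    dc <- res$cost[res$arm == "CO-PCI"] - res$cost[res$arm == "MV-PCI"]
    de <- res$effect[res$arm == "CO-PCI"] - res$effect[res$arm == "MV-PCI"]
    dplyr::mutate(compute_icer(dc, de), analysis = nm, .before = 1)
  })
  structure(list(
    cohort = cohort, breakdown = breakdown, arm_costs = arm_costs,
    year1_costs = year1_costs, tree = tree,
    utility_model = utility_model, utility_model_lt = utility_model_lt,
    cost_model = cost_model,
    death_fit = death_fit, hf_fit = hf_fit, mace_fit = mace_fit,
    utilities = utilities, markov = markov, mix = mix,
    discount = discount, horizon_age = horizon_age,
    year1 = year1, lifelong = lifelong,
    results = results, icers = dplyr::bind_rows(icers)
  ), class = "cua_pipeline")
}

# marginal per-state predictions: predict each patient under every state
# and average -- the state value at the cohort's covariate distribution
state_values_marginal <- function(model, cohort) {
  nd <- dplyr::select(cohort, "age_group", "male", "diabetes", "bmi_class",
                      "cvd_history", "risk_factor")
  nd$wave <- factor("12m", c("30d", "6m", "12m"))
  states <- c("AS", "HF", "MACE", "RF")
  out <- vapply(states, function(s) {
    nd$state <- factor(s, levels = states)
    mean(stats::predict(model$fit, newdata = nd, re.form = NA))
  }, numeric(1))
  if (model$response == "utility") {
    out <- pmin(pmax(out, model$utility_range[1]), model$utility_range[2])
  }
  out
}

#' @export
print.cua_pipeline <- function(x, ...) {
  cat("Cost-utility pipeline (", nrow(x$cohort), " patients)\n", sep = "")
  cat("Survival families: death=", x$death_fit$family,
      ", heart failure=", x$hf_fit$family,
      ", MACE=", x$mace_fit$family, "\n", sep = "")
  print(x$icers)
  invisible(x)
}

# ---- probabilistic sensitivity analysis over a fitted pipeline ----------

#' Parameter uncertainty of a fitted pipeline
#'
#' Builds the `uncertainty_spec` for [run_psa()] from the fitted pipeline,
#' with the conventional families: Beta from event counts for the absolute
#' risks (30-day mortality, conditional endpoint probabilities of the
#' MV-PCI baseline), lognormal for the relative risks, gamma for the
#' per-arm one-year mean costs and the monthly state costs, Beta for
#' utilities and shifted Beta for the incremental (state-offset)
#' utilities, and lognormal hazard multipliers for the three long-term
#' transitions (scale: the SE of the fitted log-hazard intercept).
#'
#' @param pl a [cua_pipeline()] object.
#' @return tibble understood by [run_psa()].
#' @export
psa_spec_from_pipeline <- function(pl) {
  tree <- pl$tree
  rr <- tree$rr
  rr_rows <- purrr::map(seq_len(nrow(rr)), function(i) {
    # mean-matched lognormal: centred on the point estimate like the
    # moment-matched beta and gamma draws
    psa_lognormal(paste0("rr_", rr$endpoint[i]),
                  log(rr$rr[i]) - rr$se_log_rr[i]^2 / 2,
                  rr$se_log_rr[i])
  })
  cc <- tree$conditional_counts
  q_rows <- purrr::map(setdiff(.endpoints, "as"), function(e) {
    psa_beta_counts(paste0("q_mv_", e), cc$`MV-PCI`[cc$endpoint == e],
                    tree$survivors_30d[["MV-PCI"]])
  })
  ac <- pl$arm_costs
  u30 <- pl$utilities$u30
  n30 <- vapply(.arms, function(a) {
    sum(!is.na(pl$cohort$eq5d_30d[pl$cohort$arm == a]))
  }, numeric(1))
  sd30 <- vapply(.arms, function(a) {
    stats::sd(pl$cohort$eq5d_30d[pl$cohort$arm == a], na.rm = TRUE)
  }, numeric(1))
  um <- coef_table(pl$utility_model)
  um_lt <- coef_table(pl$utility_model_lt)
  cm <- coef_table(pl$cost_model)
  su <- pl$utilities$state
  smc <- pl$markov$costs_monthly
  cost_rows <- purrr::map(.markov_states, function(s) {
    m <- smc[[s]]
    se <- if (s == "AS") cm$se[cm$term == "(Intercept)"] / 6 else
      cm$se[cm$term == paste0("state", s)] / 6
    if (m > 0) psa_gamma(paste0("cm_", tolower(s)), m, se) else
      psa_fixed(paste0("cm_", tolower(s)), m)
  })
  dplyr::bind_rows(
    psa_beta_counts("p30_mv", tree$deaths_30d[["MV-PCI"]], tree$n[["MV-PCI"]]),
    dplyr::bind_rows(rr_rows),
    dplyr::bind_rows(q_rows),
    psa_gamma("cost_co", ac$mean_total[ac$arm == "CO-PCI"],
              ac$se_total[ac$arm == "CO-PCI"]),
    psa_gamma("cost_mv", ac$mean_total[ac$arm == "MV-PCI"],
              ac$se_total[ac$arm == "MV-PCI"]),
    psa_beta("u30_co", u30[["CO-PCI"]], sd30[["CO-PCI"]] / sqrt(n30[["CO-PCI"]])),
    psa_beta("u30_mv", u30[["MV-PCI"]], sd30[["MV-PCI"]] / sqrt(n30[["MV-PCI"]])),
    psa_beta("u_as", min(su[["AS"]], 0.999),
             um$se[um$term == "(Intercept)"]),
    psa_beta_shifted("du_hf", su[["HF"]] - su[["AS"]],
                     um$se[um$term == "stateHF"]),
    psa_beta_shifted("du_mace", su[["MACE"]] - su[["AS"]],
                     um$se[um$term == "stateMACE"]),
    psa_beta_shifted("du_rf", su[["RF"]] - su[["AS"]],
                     um$se[um$term == "stateRF"]),
    psa_beta_shifted("du_mace_lt",
                     pl$markov$utilities[["MACE"]] - pl$markov$utilities[["AS"]],
                     um_lt$se[um_lt$term == "stateMACE"]),
    psa_lognormal("hm_death", -min(intercept_se(pl$death_fit), 0.7)^2 / 2,
                  min(intercept_se(pl$death_fit), 0.7)),
    psa_lognormal("hm_hf", -min(intercept_se(pl$hf_fit), 0.7)^2 / 2,
                  min(intercept_se(pl$hf_fit), 0.7)),
    psa_lognormal("hm_mace", -min(intercept_se(pl$mace_fit), 0.7)^2 / 2,
                  min(intercept_se(pl$mace_fit), 0.7)),
    dplyr::bind_rows(cost_rows)
  )
}

coef_table <- function(panel_model) {
  s <- summary(panel_model$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], se = s[, 2])
}

# SE of the location parameter of a flexsurv fit, used as the scale of the
# lognormal hazard multiplier in the PSA
intercept_se <- function(sf) {
  res <- sf$fit$res.t
  loc <- intersect(rownames(res), c("rate", "scale", "meanlog", "mu"))[1]
  unname(res[loc, "se"])
}

#' Evaluation function for the pipeline PSA
#'
#' Precomputes the long-term transition schedules at a fixed covariate
#' profile (default: the modal cell of the cohort) and returns a
#' `model_fn` for [run_psa()]. Each draw rebuilds the decision tree from
#' the sampled risks and relative risks, applies the sampled utilities and
#' costs, scales the baseline hazard schedules by the sampled multipliers,
#' and returns per-arm lifelong cost, lifelong QALYs, within-trial QALYs
#' and the probability of avoiding the 30-day composite outcome.
#'
#' @param pl a [cua_pipeline()] object.
#' @param profile one-row tibble (`age_group`, `male`, `diabetes`,
#'   `start_age`); default: modal covariate cell.
#' @return `function(theta) -> tibble(arm, cost, qaly, qaly_1y, effect_cea)`.
#' @export
psa_model_from_pipeline <- function(pl, profile = NULL) {
  if (is.null(profile)) {
    mx <- pl$mix[order(-pl$mix$weight), ][1, ]
    profile <- tibble::tibble(age_group = mx$age_group, male = mx$male,
                              diabetes = mx$diabetes,
                              start_age = sum(pl$mix$weight * pl$mix$start_age))
  }
  horizon <- max(12L, as.integer((pl$horizon_age - profile$start_age) * 12))
  cycles <- seq_len(horizon)
  origin <- pl$markov$origin %||% 365
  base <- purrr::map(.arms, function(a) {
    nd <- tibble::tibble(arm = factor(a, .arms), age_group = profile$age_group,
                         male = profile$male, diabetes = profile$diabetes)
    d_states <- sapply(.markov_states, function(st) {
      nd$risk_state <- factor(st, levels = c("AS", "HF", "MACE", "RF"))
      p1 <- monthly_transition_probability(pl$markov$death_fit, nd, 1, origin)
      # uncapped life-table-proportional schedule; capped after scaling
      lt <- pl$markov$life_table
      ages <- floor(profile$start_age) + (cycles - 1) %/% 12
      qx <- lt$annual_death_prob[match(pmin(ages, max(lt$age)), lt$age)]
      p1 * qx / qx[1]
    })
    list(death = d_states,
         hf = monthly_transition_probability(pl$markov$hf_fit, nd, cycles, origin),
         mace = monthly_transition_probability(pl$markov$mace_fit, nd, cycles, origin))
  })
  names(base) <- .arms
  discount <- pl$discount
  u30 <- pl$utilities$u30

  function(theta) {
    q_mv_ev <- c(death = theta$q_mv_death, renal_failure = theta$q_mv_renal_failure,
                 heart_failure = theta$q_mv_heart_failure, mace = theta$q_mv_mace)
    if (sum(q_mv_ev) > 1) q_mv_ev <- q_mv_ev / sum(q_mv_ev)
    q_mv <- c(q_mv_ev, as = 1 - sum(q_mv_ev))
    rr <- c(death = theta$rr_death, renal_failure = theta$rr_renal_failure,
            heart_failure = theta$rr_heart_failure, mace = theta$rr_mace)
    q_co_ev <- q_mv_ev * rr
    if (sum(q_co_ev) > 1) q_co_ev <- q_co_ev / sum(q_co_ev)
    q_co <- c(q_co_ev, as = 1 - sum(q_co_ev))
    p30 <- c("CO-PCI" = min(1, theta$p30_mv * theta$rr_death_30d),
             "MV-PCI" = theta$p30_mv)
    su <- c(AS = theta$u_as, HF = theta$u_as + theta$du_hf,
            MACE = theta$u_as + theta$du_mace, RF = theta$u_as + theta$du_rf)
    su <- pmin(pmax(su, UTILITY_FLOOR), 1)
    su_lt <- su
    su_lt[["MACE"]] <- min(max(theta$u_as + theta$du_mace_lt, UTILITY_FLOOR), 1)
    cm <- c(theta$cm_as, theta$cm_rf, theta$cm_hf, theta$cm_mace)
    y1_cost <- c("CO-PCI" = theta$cost_co, "MV-PCI" = theta$cost_mv)
    u30_d <- c("CO-PCI" = theta$u30_co, "MV-PCI" = theta$u30_mv)
    # both arms propagated in one batched Markov run (rows = arms)
    qaly1 <- c(tree_arm_qaly(p30[["CO-PCI"]], q_co, u30_d[["CO-PCI"]], su),
               tree_arm_qaly(p30[["MV-PCI"]], q_mv, u30_d[["MV-PCI"]], su))
    alive_share <- c((1 - p30[["CO-PCI"]]) * (1 - q_co[["death"]]),
                     (1 - p30[["MV-PCI"]]) * (1 - q_mv[["death"]]))
    start <- rbind(
      c(q_co[["as"]], q_co[["renal_failure"]], q_co[["heart_failure"]],
        q_co[["mace"]]),
      c(q_mv[["as"]], q_mv[["renal_failure"]], q_mv[["heart_failure"]],
        q_mv[["mace"]]))
    start <- start / rowSums(start)
    d_arm <- lapply(base, function(b) pmin(theta$hm_death * b$death, 1))
    u_row <- c(su_lt[["AS"]], su_lt[["RF"]], su_lt[["HF"]], su_lt[["MACE"]])
    lt <- markov_batch(
      d_as = cbind(d_arm[[1]][, "AS"], d_arm[[2]][, "AS"]),
      d_rf = cbind(d_arm[[1]][, "RF"], d_arm[[2]][, "RF"]),
      d_hf = cbind(d_arm[[1]][, "HF"], d_arm[[2]][, "HF"]),
      d_mace = cbind(d_arm[[1]][, "MACE"], d_arm[[2]][, "MACE"]),
      p_hf = cbind(pmin(theta$hm_hf * base[[1]]$hf, 1),
                   pmin(theta$hm_hf * base[[2]]$hf, 1)),
      p_mace = cbind(pmin(theta$hm_mace * base[[1]]$mace, 1),
                     pmin(theta$hm_mace * base[[2]]$mace, 1)),
      p_rf = matrix(0, horizon, 2),
      util = rbind(u_row, u_row, deparse.level = 0),
      cost_m = rbind(cm, cm, deparse.level = 0),
      discount = discount, start = start)
    df1 <- (1 + discount)^(-1)
    q_rf2 <- c(q_co[["renal_failure"]], q_mv[["renal_failure"]])
    p30_2 <- c(p30[["CO-PCI"]], p30[["MV-PCI"]])
    y1 <- c(y1_cost[["CO-PCI"]], y1_cost[["MV-PCI"]])
    tibble::tibble(
      arm = .arms,
      cost = as.numeric(y1 + alive_share * lt$cost * df1),
      qaly = as.numeric(qaly1 + alive_share * lt$qaly * df1),
      cost_1y = as.numeric(y1),
      qaly_1y = as.numeric(qaly1),
      effect_cea = as.numeric(1 - (p30_2 + (1 - p30_2) * q_rf2)))
  }
}
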