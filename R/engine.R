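#' One-year decision tree
#'
#' Expected undiscounted cost and QALYs per strategy for the first year.
#' The QALY convention: the first month is weighted by the 30-day utility;
#' the remaining 11 months by the utility of the one-year endpoint state;
#' 30-day deaths contribute half of the first month at the 30-day utility,
#' and patients dying between 30 days and one year contribute half of the
#' remaining 11 months at the pre-death (alive-and-stable) utility. Costs
#' are the arm-level within-trial means and are not discounted (they fall
#' in year 0-1).
#'
#' @param tree a [tree_params()] object.
#' @param utilities list with `u30` (named per-arm 30-day utility, or a
#'   single number) and `state` (named utilities for `AS`, `HF`, `MACE`,
#'   `RF`; death is 0). An optional `dying` entry overrides the utility
#'   applied to the half interval of 30-day-to-1-year decedents.
#' @param year1_costs named per-arm mean one-year cost.
#' @return tibble of class `ce_result`: `arm`, `cost`, `qaly`, and
#'   `p_death_rf_30d`, the probability of the composite death / renal
#'   failure outcome used by the 30-day cost-effectiveness analysis
#'   (30-day death plus renal replacement among survivors).
#' @export
run_decision_tree <- function(tree, utilities, year1_costs) {
  su <- utilities$state
  stopifnot(all(c("AS", "HF", "MACE", "RF") %in% names(su)))
  u_dying <- utilities$dying %||% su[["AS"]]
  rows <- purrr::map(.arms, function(a) {
    pr <- tree_arm_probs(tree, a)
    p30 <- pr$p_death_30d
    q <- pr$conditional
    assert_prob(c(p30, q), "tree probabilities")
    u30 <- if (length(utilities$u30) > 1) utilities$u30[[a]] else utilities$u30
    qaly <- tree_arm_qaly(p30, q, u30, su, u_dying)
    # composite 30-day endpoint: death or renal replacement therapy
    p_rf30 <- q[["renal_failure"]]  # RRT starts early (first days); survivors on RRT
    tibble::tibble(arm = a, cost = year1_costs[[a]], qaly = qaly,
                   p_death_rf_30d = p30 + (1 - p30) * p_rf30)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ce_result", class(out))
  out
}

# expected first-year QALY of one arm under the tree timing convention
tree_arm_qaly <- function(p30, q, u30, su, u_dying = su[["AS"]]) {
  w_state <- q[["renal_failure"]] * su[["RF"]] +
    q[["heart_failure"]] * su[["HF"]] +
    q[["mace"]] * su[["MACE"]] +
    q[["as"]] * su[["AS"]] +
    q[["death"]] * 0.5 * u_dying
  p30 * 0.5 * (1 / 12) * u30 +
    (1 - p30) * ((1 / 12) * u30 + (11 / 12) * w_state)
}

#' Life-table proportional mortality schedule
#'
#' The survival model predicts the death probability of the first Markov
#' cycle only; thereafter the monthly probability scales proportionally to
#' the age-specific annual mortality of a life table:
#' `p(c) = min(1, p1 * q(age at cycle c) / q(age at cycle 1))`, with age
#' advancing one year every 12 cycles. Ages beyond the table reuse its last
#' entry.
#'
#' @param first_cycle_prob monthly death probability at cycle 1.
#' @param life_table data frame with columns `age`, `annual_death_prob`.
#' @param start_age age (years) at cycle 1.
#' @param horizon number of cycles.
#' @return numeric vector of length `horizon`.
#' @export
build_mortality_schedule <- function(first_cycle_prob, life_table, start_age,
                                     horizon) {
  assert_prob(first_cycle_prob, "first_cycle_prob")
  ages <- floor(start_age) + (seq_len(horizon) - 1) %/% 12
  q <- life_table$annual_death_prob[
    pmin(match(pmin(ages, max(life_table$age)), life_table$age),
         nrow(life_table))]
  if (anyNA(q)) stop_config("life table does not cover ages %d-%d",
                            min(ages), max(ages))
  if (q[1] == 0) stop_config("life-table mortality is zero at the start age")
  pmin(1, first_cycle_prob * q / q[1])
}

#' Long-term Markov specification
#'
#' Builds the five-state monthly-cycle structure (`AS`, `RF`, `HF`,
#' `MACE`, `DEATH`) from per-cycle transition probabilities. Death is
#' absorbing; only alive-and-stable patients can develop renal or heart
#' failure (and by default long-term renal-failure incidence is zero: no
#' new renal replacement was observed after the acute phase); any living
#' state can suffer a MACE; a MACE patient either dies, suffers a
#' recurrence (stays in `MACE` one more cycle), or returns to `AS`. When
#' incidence probabilities from a living state would exceed the survival
#' probability of the cycle they are rescaled to fit.
#'
#' @param p_death per-cycle death probability: matrix `horizon x 4` with
#'   columns `AS`, `RF`, `HF`, `MACE`, or a vector/scalar recycled across
#'   states.
#' @param p_hf,p_mace,p_rf per-cycle incidence probabilities (length
#'   `horizon` or 1).
#' @param utilities named annual QALY weights for the four living states
#'   (`DEATH` is 0).
#' @param costs_monthly named euro cost per cycle for the living states.
#' @param discount annual discount rate.
#' @param horizon number of cycles.
#' @return object of class `markov_spec` with a `transitions(cycle)`
#'   function returning the 5x5 transition matrix.
#' @export
markov_spec <- function(p_death, p_hf = 0, p_mace = 0, p_rf = 0,
                        utilities, costs_monthly = c(AS = 0, RF = 0, HF = 0, MACE = 0),
                        discount = 0.03, horizon = 12 * 40) {
  states <- c(.markov_states, "DEATH")
  if (is.null(dim(p_death))) {
    p_death <- matrix(rep(p_death, length.out = horizon), horizon, 4)
  }
  colnames(p_death) <- .markov_states
  rep_h <- function(x) rep(x, length.out = horizon)
  p_hf <- rep_h(p_hf); p_mace <- rep_h(p_mace); p_rf <- rep_h(p_rf)
  u <- c(utilities[.markov_states], DEATH = 0)
  cm <- c(costs_monthly[.markov_states], DEATH = 0)
  transitions <- function(cycle) {
    markov_transition_matrix(p_death[cycle, ], p_hf[cycle], p_mace[cycle],
                             p_rf[cycle])
  }
  structure(list(states = states, transitions = transitions,
                 utilities = stats::setNames(as.numeric(u), states),
                 costs_monthly = stats::setNames(as.numeric(cm), states),
                 discount = discount, horizon = horizon),
            class = "markov_spec")
}

markov_transition_matrix <- function(d, p_hf, p_mace, p_rf) {
  s <- c(.markov_states, "DEATH")
  P <- matrix(0, 5, 5, dimnames = list(s, s))
  # AS: competing incidences squeezed into the survival probability
  inc <- c(RF = p_rf, HF = p_hf, MACE = p_mace)
  room <- 1 - d[["AS"]]
  if (sum(inc) > room) inc <- inc * room / sum(inc)
  P["AS", ] <- c(AS = room - sum(inc), inc, DEATH = d[["AS"]])[s]
  for (st in c("RF", "HF")) {
    pm <- min(p_mace, 1 - d[[st]])
    P[st, st] <- 1 - d[[st]] - pm
    P[st, "MACE"] <- pm
    P[st, "DEATH"] <- d[[st]]
  }
  pm <- min(p_mace, 1 - d[["MACE"]])
  P["MACE", "MACE"] <- pm                      # recurrence
  P["MACE", "AS"] <- 1 - d[["MACE"]] - pm      # reset to alive-and-stable
  P["MACE", "DEATH"] <- d[["MACE"]]
  P["DEATH", "DEATH"] <- 1
  P
}

#' Run a Markov cohort model
#'
#' Synchronous cohort propagation: transitions happen at the beginning of
#' each cycle and payoffs accrue in the post-transition state for 1/12 of a
#' year, discounted by `(1 + rate)^(-cycle / 12)`. No half-cycle
#' correction is applied (the model's stated timing convention). The run
#' terminates at the horizon or when the living mass drops below `1e-9`.
#'
#' Accepts a [markov_spec()] or any list with elements `states`,
#' `transitions` (constant matrix or `function(cycle)`), `utilities`,
#' `costs_monthly`, `discount`, `horizon`, so arbitrary small chains can be
#' checked against independent oracles.
#'
#' @param spec the model specification.
#' @param start named start distribution over `spec$states` (sums to 1).
#' @return tibble of class `cohort_trace`: one row per cycle with the
#'   state occupancy, discounted cycle increments `cost` and `qaly`, and
#'   running totals `cum_cost`, `cum_qaly`.
#' @export
run_markov <- function(spec, start) {
  states <- spec$states
  stopifnot(setequal(names(start), states))
  occ <- as.numeric(start[states])
  assert_prob_vector(occ, "start", tol = 1e-10)
  trans <- spec$transitions
  get_P <- if (is.function(trans)) trans else function(cycle) trans
  u <- spec$utilities[states]
  cm <- spec$costs_monthly[states]
  r <- spec$discount
  rows <- vector("list", spec$horizon)
  cum_cost <- cum_qaly <- 0
  dead <- states == "DEATH"
  for (cycle in seq_len(spec$horizon)) {
    P <- get_P(cycle)
    check_transition_matrix(P, states, cycle)
    occ <- as.numeric(occ %*% P)
    df <- (1 + r)^(-cycle / 12)
    qaly <- sum(occ * u) / 12 * df
    cost <- sum(occ * cm) * df
    cum_cost <- cum_cost + cost
    cum_qaly <- cum_qaly + qaly
    rows[[cycle]] <- c(cycle, occ, cost, qaly, cum_cost, cum_qaly)
    if (sum(occ[!dead]) < 1e-9) break
  }
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- tibble::as_tibble(as.data.frame(rows))
  names(out) <- c("cycle", states, "cost", "qaly", "cum_cost", "cum_qaly")
  class(out) <- c("cohort_trace", class(out))
  out
}

check_transition_matrix <- function(P, states, cycle) {
  if (any(abs(rowSums(P) - 1) > 1e-10) || any(P < -1e-12) || any(P > 1 + 1e-12)) {
    stop_config("invalid transition matrix at cycle %d (rows must sum to 1)",
                cycle)
  }
  invisible(P)
}

# vectorised core used by the probabilistic sensitivity analysis: R
# independent runs share the 4+1 state structure; matrices are [cycles x R]
# for probabilities and [R x 4] for start/utilities/costs. Returns per-run
# discounted totals. Kept in exact agreement with run_markov() (tested).
markov_batch <- function(d_as, d_rf, d_hf, d_mace, p_hf, p_mace, p_rf,
                         util, cost_m, discount, start) {
  R <- nrow(start)
  H <- nrow(d_as)
  as_ <- start[, 1]; rf <- start[, 2]; hf <- start[, 3]; mace <- start[, 4]
  qaly <- cost <- numeric(R)
  for (c in seq_len(H)) {
    inc_sum <- p_rf[c, ] + p_hf[c, ] + p_mace[c, ]
    room <- 1 - d_as[c, ]
    sc <- ifelse(inc_sum > room, room / pmax(inc_sum, 1e-300), 1)
    i_rf <- p_rf[c, ] * sc; i_hf <- p_hf[c, ] * sc; i_mace <- p_mace[c, ] * sc
    pm_rf <- pmin(p_mace[c, ], 1 - d_rf[c, ])
    pm_hf <- pmin(p_mace[c, ], 1 - d_hf[c, ])
    pm_m <- pmin(p_mace[c, ], 1 - d_mace[c, ])
    as_n <- as_ * (room - i_rf - i_hf - i_mace) + mace * (1 - d_mace[c, ] - pm_m)
    rf_n <- rf * (1 - d_rf[c, ] - pm_rf) + as_ * i_rf
    hf_n <- hf * (1 - d_hf[c, ] - pm_hf) + as_ * i_hf
    mace_n <- as_ * i_mace + rf * pm_rf + hf * pm_hf + mace * pm_m
    as_ <- as_n; rf <- rf_n; hf <- hf_n; mace <- mace_n
    df <- (1 + discount)^(-c / 12)
    qaly <- qaly + (as_ * util[, 1] + rf * util[, 2] + hf * util[, 3] +
                      mace * util[, 4]) / 12 * df
    cost <- cost + (as_ * cost_m[, 1] + rf * cost_m[, 2] + hf * cost_m[, 3] +
                      mace * cost_m[, 4]) * df
  }
  tibble::tibble(qaly = qaly, cost = cost)
}

#' Cohort covariate mixture for the lifelong evaluation
#'
#' Cells of the age-group x sex x diabetes cross-classification with their
#' cohort frequencies and the mean age at which survivors would enter the
#' Markov stage (one year after randomisation).
#'
#' @param cohort a cohort tibble.
#' @return tibble: `age_group`, `male`, `diabetes`, `weight`, `start_age`.
#' @export
covariate_mix <- function(cohort) {
  dplyr::summarise(
    dplyr::group_by(cohort, .data$age_group, .data$male, .data$diabetes),
    weight = dplyr::n() / nrow(cohort),
    start_age = mean(.data$age_years) + 1,
    .groups = "drop")
}

#' Lifelong evaluation: decision tree chained to the Markov model
#'
#' Year one comes from [run_decision_tree()]; one-year survivors enter the
#' Markov stage distributed over the living states according to the tree's
#' conditional endpoint probabilities, and accrue discounted cost and QALYs
#' until the horizon age. Markov accruals are additionally discounted by
#' one year, their offset from randomisation. Results are aggregated over
#' the covariate mixture.
#'
#' @param tree a [tree_params()] object.
#' @param utilities as in [run_decision_tree()].
#' @param year1_costs named per-arm mean one-year cost.
#' @param markov list describing the long-term stage: `death_fit`,
#'   `hf_fit`, `mace_fit` (objects accepted by
#'   [monthly_transition_probability()]), `life_table`, `utilities`
#'   (named, long-term state utilities -- typically with the redefined MACE
#'   utility), `costs_monthly` (named), and optionally `p_rf` (default 0:
#'   no long-term renal-failure incidence) and `origin` (day the first
#'   cycle starts, default 365).
#' @param mix a [covariate_mix()] tibble.
#' @param discount annual discount rate.
#' @param horizon_age run each cell to this age.
#' @return tibble of class `ce_result`: per arm `cost`, `qaly`, with the
#'   year-one (`cost_year1`, `qaly_year1`) and long-term components, and
#'   the 30-day composite probability.
#' @export
lifelong_evaluation <- function(tree, utilities, year1_costs, markov, mix,
                                discount = 0.03, horizon_age = 100) {
  year1 <- run_decision_tree(tree, utilities, year1_costs)
  lt_u <- markov$utilities
  stopifnot(all(.markov_states %in% names(lt_u)),
            all(.markov_states %in% names(markov$costs_monthly)))
  rows <- purrr::map(.arms, function(a) {
    pr <- tree_arm_probs(tree, a)
    q <- pr$conditional
    alive_share <- (1 - pr$p_death_30d) * (1 - q[["death"]])
    start <- c(AS = q[["as"]], RF = q[["renal_failure"]],
               HF = q[["heart_failure"]], MACE = q[["mace"]])
    start <- start / sum(start)
    cell_tot <- purrr::pmap(mix, function(age_group, male, diabetes, weight,
                                          start_age, ...) {
      horizon <- max(12L, as.integer((horizon_age - start_age) * 12))
      spec <- cell_markov_spec(markov, a, age_group, male, diabetes,
                               start_age, horizon, lt_u, discount)
      trace <- run_markov(spec, c(start, DEATH = 0))
      weight * c(cost = trace$cum_cost[nrow(trace)],
                 qaly = trace$cum_qaly[nrow(trace)])
    })
    tot <- Reduce(`+`, cell_tot)
    y1 <- year1[year1$arm == a, ]
    df1 <- (1 + discount)^(-1)  # Markov stage starts one year after randomisation
    tibble::tibble(
      arm = a,
      cost_year1 = y1$cost, qaly_year1 = y1$qaly,
      cost_longterm = alive_share * tot[["cost"]] * df1,
      qaly_longterm = alive_share * tot[["qaly"]] * df1,
      cost = cost_year1 + cost_longterm,
      qaly = qaly_year1 + qaly_longterm,
      p_death_rf_30d = y1$p_death_rf_30d
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ce_result", class(out))
  out
}

#' Per-arm closed-form hazards for the Markov stage
#'
#' Wraps one [parametric_hazard()] (or fitted model) per arm so the
#' lifelong evaluation can run from calibrated closed-form hazards instead
#' of regression fits (the covariate profile is then ignored).
#'
#' @param co,mv hazard model for each arm.
#' @export
arm_hazards <- function(co, mv) {
  structure(list("CO-PCI" = co, "MV-PCI" = mv), class = "arm_hazards")
}

hazard_for_arm <- function(object, arm) {
  if (inherits(object, "arm_hazards")) object[[arm]] else object
}

# per-cell Markov spec: first-cycle death probabilities by state scaled by
# the life table; HF/MACE incidence evaluated from the fitted hazards over
# the whole horizon
cell_markov_spec <- function(markov, arm, age_group, male, diabetes,
                             start_age, horizon, utilities, discount) {
  origin <- markov$origin %||% 365
  nd <- tibble::tibble(arm = factor(arm, .arms),
                       age_group = age_group, male = male, diabetes = diabetes)
  death_fit <- hazard_for_arm(markov$death_fit, arm)
  p_death <- sapply(.markov_states, function(st) {
    nd$risk_state <- factor(st, levels = c("AS", "HF", "MACE", "RF"))
    p1 <- monthly_transition_probability(death_fit, nd, 1,
                                         origin = origin)
    build_mortality_schedule(p1, markov$life_table, start_age, horizon)
  })
  cycles <- seq_len(horizon)
  p_hf <- monthly_transition_probability(hazard_for_arm(markov$hf_fit, arm),
                                         nd, cycles, origin = origin)
  p_mace <- monthly_transition_probability(hazard_for_arm(markov$mace_fit, arm),
                                           nd, cycles, origin = origin)
  markov_spec(p_death = p_death, p_hf = p_hf, p_mace = p_mace,
              p_rf = markov$p_rf %||% 0,
              utilities = utilities, costs_monthly = markov$costs_monthly,
              discount = discount, horizon = horizon)
}
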