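#' Relative risk and its log-scale standard error
#'
#' `relative_risk()` is the plain ratio of two proportions (CO-PCI over
#' MV-PCI throughout this package). `se_log_rr()` is the standard error of
#' the log relative risk from event counts `a / n1` and `b / n2`:
#' `sqrt(1/a - 1/n1 + 1/b - 1/n2)`.
#'
#' @param p1,p0 proportions (numerator and denominator arm).
#' @param a,n1,b,n2 event count and size of each arm.
#' @export
relative_risk <- function(p1, p0) p1 / p0

#' @rdname relative_risk
#' @export
se_log_rr <- function(a, n1, b, n2) sqrt(1 / a - 1 / n1 + 1 / b - 1 / n2)

#' Decision-tree parameters
#'
#' `estimate_tree_probabilities()` derives them from a classified cohort as
#' raw frequencies: per-arm 30-day death probability; the MV-PCI
#' conditional endpoint distribution among 30-day survivors as the
#' baseline; and per-endpoint relative risks CO-PCI / MV-PCI with log-scale
#' standard errors. Endpoints with zero MV-PCI events get a 0.5 continuity
#' correction (both arms), with a warning. `tree_params()` builds the same
#' object directly from counts, e.g. the published ones in
#' [ref_tree_counts()].
#'
#' The CO-PCI conditional probabilities implied by the object are `baseline
#' x RR` for the four event states with alive-and-stable as the residual;
#' if the events alone exceed 1 they are renormalised to sum to 1 and the
#' residual set to zero. Retrieve them with [tree_arm_probs()].
#'
#' @param cohort a cohort with `state_30d` / `state_1y` columns (see
#'   [classify_states()]); classification is run on the fly if absent.
#' @param n,deaths_30d named per-arm totals and 30-day deaths.
#' @param conditional tibble of per-arm endpoint counts among survivors
#'   (columns `endpoint`, `CO-PCI`, `MV-PCI`).
#' @return object of class `tree_params`.
#' @export
estimate_tree_probabilities <- function(cohort) {
  if (!"state_1y" %in% names(cohort)) cohort <- classify_states(cohort)
  n <- table(cohort$arm)[.arms]
  deaths_30d <- vapply(.arms, function(a) {
    sum(cohort$arm == a & cohort$state_30d == "DEATH")
  }, numeric(1))
  state_codes <- c(death = "DEATH", renal_failure = "RF", heart_failure = "HF",
                   mace = "MACE", as = "AS")
  conditional <- tibble::tibble(
    endpoint = .endpoints,
    `CO-PCI` = unname(vapply(state_codes, function(s) {
      sum(cohort$arm == "CO-PCI" & !is.na(cohort$state_1y) & cohort$state_1y == s)
    }, numeric(1))),
    `MV-PCI` = unname(vapply(state_codes, function(s) {
      sum(cohort$arm == "MV-PCI" & !is.na(cohort$state_1y) & cohort$state_1y == s)
    }, numeric(1)))
  )
  tree_params(n = stats::setNames(as.numeric(n), .arms),
              deaths_30d = deaths_30d, conditional = conditional)
}

#' @rdname estimate_tree_probabilities
#' @export
tree_params <- function(n, deaths_30d, conditional) {
  surv <- n - deaths_30d
  corrected <- conditional$`MV-PCI` == 0 | conditional$`CO-PCI` == 0
  if (any(corrected)) {
    warning("zero event count for ", paste(conditional$endpoint[corrected],
                                           collapse = ", "),
            "; applying 0.5 continuity correction", call. = FALSE)
  }
  a <- conditional$`CO-PCI` + 0.5 * corrected
  b <- conditional$`MV-PCI` + 0.5 * corrected
  n1 <- surv[["CO-PCI"]] + 0.5 * corrected
  n2 <- surv[["MV-PCI"]] + 0.5 * corrected
  rr <- tibble::tibble(
    endpoint = conditional$endpoint,
    rr = (a / n1) / (b / n2),
    se_log_rr = se_log_rr(a, n1, b, n2)
  )
  # 30-day death RR and its SE
  rr30 <- tibble::tibble(
    endpoint = "death_30d",
    rr = (deaths_30d[["CO-PCI"]] / n[["CO-PCI"]]) /
      (deaths_30d[["MV-PCI"]] / n[["MV-PCI"]]),
    se_log_rr = se_log_rr(deaths_30d[["CO-PCI"]], n[["CO-PCI"]],
                          deaths_30d[["MV-PCI"]], n[["MV-PCI"]])
  )
  structure(list(
    n = n, deaths_30d = deaths_30d, survivors_30d = surv,
    p_death_30d = deaths_30d / n,
    baseline = stats::setNames(
      if (surv[["MV-PCI"]] > 0) conditional$`MV-PCI` / surv[["MV-PCI"]]
      else rep(0, nrow(conditional)),
      conditional$endpoint),
    conditional_counts = conditional,
    rr = dplyr::bind_rows(rr30, rr)
  ), class = "tree_params")
}

#' Per-arm decision-tree probabilities implied by a `tree_params` object
#'
#' @param tree a [tree_params()] object.
#' @param arm `"CO-PCI"` or `"MV-PCI"`.
#' @return list with `p_death_30d` and the named conditional endpoint
#'   probability vector (sums to 1).
#' @export
tree_arm_probs <- function(tree, arm) {
  if (arm == "MV-PCI") {
    probs <- tree$baseline
  } else {
    rr <- stats::setNames(tree$rr$rr, tree$rr$endpoint)
    ev <- setdiff(.endpoints, "as")
    probs <- tree$baseline[ev] * rr[ev]
    if (sum(probs) > 1) probs <- probs / sum(probs)
    probs <- c(probs, as = 1 - sum(probs))
  }
  list(p_death_30d = unname(tree$p_death_30d[[arm]]),
       conditional = probs[.endpoints])
}

#' Random-effect panel models for utilities and costs
#'
#' Linear mixed model with a patient random intercept, the health state as
#' the explanatory variable of interest (reference: alive-and-stable) and
#' the baseline covariates as controls, fitted with [lme4::lmer()].
#'
#' For `response = "utility"` the panel stacks the 30-day, 6-month and
#' 12-month EQ5D observations of patients alive at the wave; the state of a
#' row is the patient's one-year state at the 6- and 12-month waves and
#' alive-and-stable at 30 days (before state-specific experience has
#' accrued), and a follow-up-wave fixed effect absorbs the recovery trend
#' between waves. With `mace_longterm = TRUE` the long-term MACE
#' redefinition (`state_1y_lt`: urgent revascularisation / MI / stroke
#' only) is used, as for the Markov-stage MACE utility. For
#' `response = "cost"` the panel holds the 6- and 12-month follow-up
#' hospitalisation plus emergency-room cost per wave.
#'
#' @param cohort a classified cohort ([classify_states()] is applied if
#'   needed).
#' @param response `"utility"` or `"cost"`.
#' @param mace_longterm use the long-term MACE definition for the state
#'   covariate.
#' @param unit_costs unit-cost table (cost response only).
#' @return object of class `panel_model`: the `lme4` fit plus metadata.
#'   Use [state_values()] for per-state predictions and `tidy()` /
#'   `glance()` for coefficients and fit statistics.
#' @export
fit_panel_model <- function(cohort, response = c("utility", "cost"),
                            mace_longterm = FALSE,
                            unit_costs = default_unit_costs()) {
  response <- match.arg(response)
  if (!"state_1y" %in% names(cohort)) cohort <- classify_states(cohort)
  state_col <- if (mace_longterm) "state_1y_lt" else "state_1y"
  rows <- build_panel_rows(cohort, response, state_col, unit_costs)
  n_pat <- length(unique(rows$id))
  if (n_pat < 10 || nrow(rows) < 2 * 10) {
    stop_config("panel model needs >= 2 observations for >= 10 patients (got %d patients, %d rows)",
                n_pat, nrow(rows))
  }
  rows$state <- factor(rows$state, levels = c("AS", "HF", "MACE", "RF"))
  rows$wave <- factor(rows$wave, levels = c("30d", "6m", "12m"))
  fixed <- value ~ state + wave + age_group + male + diabetes + bmi_class +
    cvd_history + risk_factor
  if (response == "cost") fixed <- stats::update(fixed, . ~ . - wave)
  fit <- lme4::lmer(stats::update(fixed, . ~ . + (1 | id)), data = rows,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = lme4::.makeCC("ignore", tol = 1e-4)))
  structure(list(fit = fit, response = response, n_patients = n_pat,
                 n_obs = nrow(rows), mace_longterm = mace_longterm,
                 utility_range = c(UTILITY_FLOOR, 1)),
            class = "panel_model")
}

build_panel_rows <- function(cohort, response, state_col, unit_costs) {
  base <- dplyr::select(cohort, "id", "arm", "age_group", "male", "diabetes",
                        "bmi_class", "cvd_history", "risk_factor",
                        state = dplyr::all_of(state_col))
  if (response == "utility") {
    waves <- list("30d" = "eq5d_30d", "6m" = "eq5d_6m", "12m" = "eq5d_12m")
    rows <- purrr::map(names(waves), function(w) {
      out <- base
      out$wave <- w
      out$value <- cohort[[waves[[w]]]]
      # before the one-year window the 30-day state is alive-and-stable
      if (w == "30d") out$state <- "AS"
      out
    })
  } else {
    unit <- function(cat) unit_costs$unit_cost[unit_costs$category == cat]
    rows <- purrr::map(c("6m", "12m"), function(w) {
      out <- base
      out$wave <- w
      out$value <- cohort[[paste0("ru_inpatient_days_", w)]] * unit("inpatient_days") +
        cohort[[paste0("ru_er_visits_", w)]] * unit("er_visits")
      out
    })
  }
  rows <- dplyr::bind_rows(rows)
  rows[!is.na(rows$value) & !is.na(rows$state), ]
}

#' Predicted per-state values from a panel model
#'
#' State predictions at the reference covariate cell (or at supplied
#' covariate values), i.e. intercept + state coefficient (+ covariate
#' shift). Utilities are clipped to the valid range and the death state is
#' fixed at zero.
#'
#' @param model a [fit_panel_model()] result.
#' @param newdata optional one-row data frame of covariates (columns
#'   `age_group`, `male`, `diabetes`, `bmi_class`, `cvd_history`,
#'   `risk_factor`, and `wave` for the utility model; defaults to the
#'   reference cell at the 12-month wave).
#' @return named numeric over `AS`, `HF`, `MACE`, `RF`, `DEATH`.
#' @export
state_values <- function(model, newdata = NULL) {
  if (is.null(newdata)) {
    newdata <- tibble::tibble(age_group = factor("50-75", c("<50", "50-75", ">75")),
                              male = TRUE, diabetes = FALSE,
                              bmi_class = factor("normal_under",
                                                 c("normal_under", "overweight", "obese")),
                              cvd_history = FALSE, risk_factor = FALSE,
                              wave = factor("12m", c("30d", "6m", "12m")))
  }
  states <- c("AS", "HF", "MACE", "RF")
  nd <- newdata[rep(1, length(states)), , drop = FALSE]
  nd$state <- factor(states, levels = states)
  pred <- stats::predict(model$fit, newdata = nd, re.form = NA)
  out <- stats::setNames(as.numeric(pred), states)
  if (model$response == "utility") {
    out <- pmin(pmax(out, model$utility_range[1]), model$utility_range[2])
  }
  c(out, DEATH = 0)
}
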