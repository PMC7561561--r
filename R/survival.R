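#' Parametric survival fits for long-term extrapolation
#'
#' Fits the candidate hazard families -- exponential, Weibull, Gompertz,
#' log-logistic, log-normal -- to the 30-day-to-1-year window of the trial
#' by maximum likelihood via [flexsurv::flexsurvreg()], with left
#' truncation at day 30 (patients enter the risk set at the 30-day visit)
#' and censoring at day 365. The family minimising AIC is returned; BIC is
#' reported alongside, and AIC ties break towards the model with fewer
#' parameters. Families that fail to converge are skipped with a warning.
#'
#' The covariate set is trial arm, age group, sex and diabetes; the death
#' model additionally conditions on the health state while at risk (the
#' one-year state for survivors, the state held at death for decedents).
#'
#' @param cohort a cohort tibble; 30-day deaths are excluded from the risk
#'   set automatically.
#' @param event which transition to model: time to all-cause `death`,
#'   first `heart_failure` re-hospitalisation, or first `mace`.
#' @param families candidate families (any subset of the five).
#' @param window fit window in days, default `c(30, 365)`.
#' @param covariates right-hand-side formula of baseline covariates.
#' @return object of class `survival_fit`: the selected
#'   [flexsurv::flexsurvreg] fit (`$fit`), the selected `$family`, an
#'   information-criterion comparison table (`$ic`) and the fit window.
#' @export
fit_survival <- function(cohort,
                         event = c("death", "heart_failure", "mace"),
                         families = c("exponential", "weibull", "gompertz",
                                      "loglogistic", "lognormal"),
                         window = c(30, 365),
                         covariates = ~ arm + age_group + male + diabetes) {
  event <- match.arg(event)
  dat <- survival_dataset(cohort, event, window)
  if (sum(dat$status) < 2) {
    stop_config("fewer than 2 '%s' events in the fit window", event)
  }
  rhs <- covariates
  if (event == "death") rhs <- stats::update(rhs, ~ . + risk_state)
  # drop covariates that are constant in the risk set (degenerate contrasts)
  keep <- Filter(function(v) length(unique(dat[[v]])) > 1, all.vars(rhs))
  rhs <- if (length(keep)) {
    stats::reformulate(keep)
  } else {
    ~ 1
  }
  form <- stats::update(rhs, survival::Surv(tstart, tstop, status) ~ .)
  dist_map <- c(exponential = "exp", weibull = "weibull", gompertz = "gompertz",
                loglogistic = "llogis", lognormal = "lnorm")
  fams <- match.arg(families, names(dist_map), several.ok = TRUE)
  fits <- list()
  for (fam in fams) {
    fits[[fam]] <- tryCatch(
      flexsurv::flexsurvreg(form, data = dat, dist = dist_map[[fam]]),
      error = function(e) {
        warning(sprintf("%s fit failed for '%s': %s", fam, event,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
  }
  fits <- purrr::compact(fits)
  if (!length(fits)) stop_config("no survival family converged for '%s'", event)
  ic <- tibble::tibble(
    family = names(fits),
    npar = vapply(fits, function(f) f$npars, numeric(1)),
    logLik = vapply(fits, function(f) f$loglik, numeric(1)),
    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
    BIC = vapply(fits, function(f) -2 * f$loglik + log(f$N) * f$npars, numeric(1))
  )
  best <- ic[order(ic$AIC, ic$npar), ][1, ]
  structure(list(fit = fits[[best$family]], family = best$family, ic = ic,
                 event = event, window = window), class = "survival_fit")
}

# risk-set dataset: entry at day 30 (or first event day if modelling a
# non-death event, patients exit at the event, death or day 365)
survival_dataset <- function(cohort, event, window) {
  alive30 <- is.na(cohort$death_time) | cohort$death_time > window[1]
  dat <- cohort[alive30, ]
  death_t <- ifelse(is.na(dat$death_time), window[2], dat$death_time)
  ev_time <- switch(event,
    death = death_t,
    heart_failure = ifelse(is.na(dat$hf_time), Inf, dat$hf_time),
    mace = first_mace_day(dat$mace_events)
  )
  tstop <- pmin(ev_time, death_t, window[2])
  status <- as.integer(ev_time <= pmin(death_t, window[2]))
  if (event == "death") {
    status <- as.integer(!is.na(dat$death_time) & dat$death_time <= window[2])
  }
  out <- tibble::tibble(
    tstart = window[1], tstop = pmax(tstop, window[1] + 1e-6),
    status = status,
    arm = factor(dat$arm, levels = .arms),
    age_group = dat$age_group, male = dat$male, diabetes = dat$diabetes
  )
  if (event == "death") {
    out$risk_state <- factor(interim_state(dat), levels = c("AS", "HF", "MACE", "RF"))
  }
  out[out$tstop > out$tstart, ]
}

#' Survival probability from a fitted or specified parametric model
#'
#' `surv_at()` evaluates S(t). `monthly_transition_probability()` converts
#' a survival model into the per-cycle transition probability of a monthly
#' Markov model: `p = 1 - S(t + delta) / S(t)` with `delta = 30.4375` days
#' (365.25 / 12), where `t` is the time at the start of cycle
#' `cycle_index` measured from `origin` (days since randomisation, default
#' 365: the Markov stage starts when the decision tree ends). Returns 1
#' where `S(t)` is zero.
#'
#' Both accept a `survival_fit`, a raw `flexsurvreg` object, or a
#' `parametric_hazard()` specification (family plus parameter list), so
#' closed-form toy models can drive the engine in tests.
#'
#' @param object model, see above.
#' @param t time in days.
#' @param newdata one-row data frame of covariates for regression fits.
#' @param cycle_index cycle number (>= 1).
#' @param origin day at which cycle 1 starts.
#' @param cycle_days days per cycle.
#' @return probability (vectorised over `cycle_index`).
#' @export
monthly_transition_probability <- function(object, newdata = NULL,
                                           cycle_index = 1, origin = 365,
                                           cycle_days = CYCLE_DAYS) {
  stopifnot(all(cycle_index >= 1))
  t0 <- origin + (cycle_index - 1) * cycle_days
  s0 <- surv_at(object, t0, newdata)
  s1 <- surv_at(object, t0 + cycle_days, newdata)
  p <- ifelse(s0 <= 0, 1, pmin(pmax(1 - s1 / s0, 0), 1))
  unname(p)
}

#' @rdname monthly_transition_probability
#' @export
surv_at <- function(object, t, newdata = NULL) {
  if (inherits(object, "survival_fit")) object <- object$fit
  if (inherits(object, "flexsurvreg")) {
    s <- summary(object, newdata = newdata, t = t, type = "survival",
                 ci = FALSE, tidy = TRUE)
    return(s$est)
  }
  if (inherits(object, "parametric_hazard")) {
    return(do.call(object$sfun, c(list(t), object$params)))
  }
  stop_config("unsupported survival object of class %s", class(object)[1])
}

#' @rdname monthly_transition_probability
#' @param family one of `exponential`, `weibull`, `gompertz`,
#'   `loglogistic`, `lognormal`.
#' @param ... family parameters (`rate`; `shape`/`scale`;
#'   `shape`/`rate`; `meanlog`/`sdlog`).
#' @export
parametric_hazard <- function(family, ...) {
  params <- list(...)
  sfun <- switch(family,
    exponential = function(t, rate) stats::pexp(t, rate, lower.tail = FALSE),
    weibull = function(t, shape, scale) stats::pweibull(t, shape, scale, lower.tail = FALSE),
    gompertz = function(t, shape, rate) flexsurv::pgompertz(t, shape, rate, lower.tail = FALSE),
    loglogistic = function(t, shape, scale) flexsurv::pllogis(t, shape, scale, lower.tail = FALSE),
    lognormal = function(t, meanlog, sdlog) stats::plnorm(t, meanlog, sdlog, lower.tail = FALSE),
    stop_config("unknown family '%s'", family)
  )
  structure(list(family = family, params = params, sfun = sfun),
            class = "parametric_hazard")
}
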