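#' Friction-cost valuation of productivity losses
#'
#' Values lost work time under the friction-cost method with a 60-working-day
#' (8-hour) friction period: patients who did not work before randomisation
#' have zero cost; those who left work for more than 60 days, or died before
#' age 65, cost the full friction period; a return to unpaid work costs 30
#' working days, reduced hours 10; otherwise the reported days lost are
#' valued up to the 60-day cap. Vectorised.
#'
#' @param work_days_lost non-negative days of work lost.
#' @param worked_before did the patient work before randomisation?
#' @param return_to_work one of `none`, `unpaid`, `reduced_hours`, `full`.
#' @param died_before_65 death before age 65 within the costing horizon.
#' @param daily_cost euro value of one 8-hour working day.
#' @return euro cost, same length as the inputs.
#' @export
productivity_cost <- function(work_days_lost, worked_before, return_to_work,
                              died_before_65, daily_cost) {
  if (any(work_days_lost < 0)) stop("work_days_lost must be non-negative", call. = FALSE)
  return_to_work <- as.character(return_to_work)
  days <- dplyr::case_when(
    !worked_before ~ 0,
    died_before_65 ~ 60,
    return_to_work == "unpaid" ~ 30,
    return_to_work == "reduced_hours" ~ 10,
    TRUE ~ pmin(work_days_lost, 60)
  )
  days * daily_cost
}

#' Prorated DRG cost of angiography
#'
#' The DRG tariff covering catheter-lab work is assigned in proportion to
#' the total time the patient spent in fluoroscopy:
#' `drg_cost * minutes / reference_minutes`.
#'
#' @param total_fluoroscopy_minutes minutes in fluoroscopy (>= 0).
#' @param drg_cost euro DRG tariff.
#' @param reference_minutes fluoroscopy minutes the tariff corresponds to.
#' @return euro cost.
#' @export
angiography_cost <- function(total_fluoroscopy_minutes, drg_cost,
                             reference_minutes) {
  if (any(reference_minutes <= 0)) {
    stop_config("reference_minutes must be positive")
  }
  if (any(total_fluoroscopy_minutes < 0)) {
    stop("fluoroscopy minutes must be non-negative", call. = FALSE)
  }
  drg_cost * total_fluoroscopy_minutes / reference_minutes
}

# follow-up waves for self-reported hospital use: window of days covered
.fu_waves <- list(
  "30d" = list(start = 0, end = 30,
               fields = "ru_inpatient_days_30d"),
  "6m" = list(start = 30, end = 182.5,
              fields = c("ru_inpatient_days_6m", "ru_er_visits_6m")),
  "12m" = list(start = 182.5, end = 365,
               fields = c("ru_inpatient_days_12m", "ru_er_visits_12m"))
)

#' Impute missing self-reported hospital use
#'
#' Deterministic conditional-mean imputation for inpatient days and
#' emergency-room visits at each follow-up: a missing value is set to zero
#' when the patient died before the follow-up window opened (no
#' hospitalisation was possible); otherwise it is replaced by the mean of
#' the observed values among patients with the same survival status at that
#' follow-up (alive at the follow-up vs. died during the window). A stratum
#' with no observed values falls back to the overall observed mean for the
#' field, with a warning. Observed values are never altered.
#'
#' @param cohort cohort tibble.
#' @return the cohort with missing hospital-use quantities filled in and an
#'   `imputation_log` attribute (tibble: `field`, `stratum`, `n_imputed`,
#'   `imputed_value`).
#' @export
impute_missing_hospital_use <- function(cohort) {
  log <- list()
  for (wname in names(.fu_waves)) {
    w <- .fu_waves[[wname]]
    died_before <- !is.na(cohort$death_time) & cohort$death_time <= w$start
    died_during <- !is.na(cohort$death_time) & cohort$death_time > w$start &
      cohort$death_time <= w$end
    alive <- !died_before & !died_during
    for (f in intersect(w$fields, names(cohort))) {
      x <- cohort[[f]]
      miss <- is.na(x)
      if (!any(miss)) next
      x[miss & died_before] <- 0
      strata <- list(alive = alive, died_during = died_during)
      for (sname in names(strata)) {
        s <- strata[[sname]]
        idx <- miss & s
        if (!any(idx)) next
        obs <- x[s & !miss]
        if (length(obs) == 0) {
          obs <- cohort[[f]][!miss]
          warning(sprintf("no observed values for %s in stratum '%s'; using overall mean",
                          f, sname), call. = FALSE)
        }
        x[idx] <- mean(obs)
        log[[length(log) + 1]] <- tibble::tibble(
          field = f, stratum = sname, n_imputed = sum(idx),
          imputed_value = mean(obs))
      }
      if (any(miss & died_before)) {
        log[[length(log) + 1]] <- tibble::tibble(
          field = f, stratum = "died_before", n_imputed = sum(miss & died_before),
          imputed_value = 0)
      }
      cohort[[f]] <- x
    }
  }
  attr(cohort, "imputation_log") <-
    if (length(log)) dplyr::bind_rows(log) else
      tibble::tibble(field = character(), stratum = character(),
                     n_imputed = integer(), imputed_value = numeric())
  cohort
}

#' Per-patient one-year cost breakdown
#'
#' Multiplies each resource quantity by its unit cost and applies the
#' trial-specific rules: 30-day self-reported inpatient days are excluded
#' (they double-count the eCRF index hospitalisation); fluoroscopy minutes
#' are valued as a prorated DRG via [angiography_cost()]; medications cost
#' days-at-standard-dose times the daily price; renal replacement adds the
#' annual dialysis cost only for patients alive at day 365; productivity
#' losses follow [productivity_cost()].
#'
#' @param cohort cohort tibble (imputation already applied; remaining `NA`
#'   quantities are an error).
#' @param unit_costs unit-cost table, see [default_unit_costs()].
#' @param drg_cost,reference_minutes angiography DRG proration settings;
#'   the defaults reproduce the `fluoro_minutes` per-minute tariff of
#'   [default_unit_costs()].
#' @return tibble of class `cost_breakdown`: `id`, `arm`, one `cost_*`
#'   column per category, `total`.
#' @export
patient_total_cost <- function(cohort, unit_costs = default_unit_costs(),
                               drg_cost = 2320, reference_minutes = 100) {
  ru_cols <- grep("^ru_", names(cohort), value = TRUE)
  cats <- sub("^ru_", "", ru_cols)
  unknown <- setdiff(unique(base_category(cats)),
                     c(unit_costs$category, "fluoro_minutes"))
  if (length(unknown)) {
    stop_config("no unit cost for resource categor%s: %s",
                if (length(unknown) > 1) "ies" else "y",
                paste(unknown, collapse = ", "))
  }
  out <- tibble::tibble(id = cohort$id, arm = cohort$arm)
  excluded <- "inpatient_days_30d"  # self-reported, double-counts the index stay
  for (i in seq_along(ru_cols)) {
    cat <- cats[i]
    q <- cohort[[ru_cols[i]]]
    if (anyNA(q)) {
      stop_config("missing quantities in %s; run impute_missing_hospital_use() first",
                  ru_cols[i])
    }
    cost <- if (base_category(cat) == "fluoro_minutes") {
      angiography_cost(q, drg_cost, reference_minutes)
    } else {
      q * unit_costs$unit_cost[unit_costs$category == base_category(cat)]
    }
    if (cat %in% excluded) cost <- 0 * cost
    out[[paste0("cost_", cat)]] <- cost
  }
  alive_1y <- is.na(cohort$death_time)
  out$cost_dialysis_year <- ifelse(cohort$renal_replacement & alive_1y,
                                   unit_costs$unit_cost[unit_costs$category == "dialysis_year"],
                                   0)
  died_before_65 <- !is.na(cohort$death_time) &
    (cohort$age_years + cohort$death_time / 365.25) < 65
  out$cost_productivity <- productivity_cost(
    cohort$work_days_lost, cohort$worked_before, cohort$return_to_work,
    died_before_65,
    unit_costs$unit_cost[unit_costs$category == "work_day"])
  cost_cols <- grep("^cost_", names(out), value = TRUE)
  out$total <- rowSums(out[cost_cols])
  class(out) <- c("cost_breakdown", class(out))
  out
}

#' Flag and remove outlying resource quantities
#'
#' Screens each `ru_*` column and blanks values beyond the configured
#' threshold so they re-enter the conditional-mean imputation. The default
#' rule drops values above the 99.9th percentile of the positive values of
#' the category; `method = "iqr"` uses `Q3 + k * IQR` of the positive
#' values instead.
#'
#' @param cohort cohort tibble.
#' @param rule list: `method` (`"quantile"` or `"iqr"`), `quantile`
#'   (default 0.999) or `k` (default 3).
#' @param fields resource columns to screen; defaults to every `ru_*`
#'   column. The pipeline restricts screening to the self-reported
#'   follow-up quantities, whose blanked values re-enter
#'   [impute_missing_hospital_use()].
#' @return the cohort with outliers set to `NA` and a `trim_log` attribute
#'   (tibble: `field`, `threshold`, `n_removed`).
#' @export
trim_outliers <- function(cohort, rule = list(method = "quantile",
                                              quantile = 0.999),
                          fields = NULL) {
  ru_cols <- fields %||% grep("^ru_", names(cohort), value = TRUE)
  log <- list()
  for (f in ru_cols) {
    x <- cohort[[f]]
    pos <- x[!is.na(x) & x > 0]
    if (length(pos) < 10) next
    thr <- switch(rule$method %||% "quantile",
      quantile = stats::quantile(pos, rule$quantile %||% 0.999, names = FALSE),
      iqr = {
        qs <- stats::quantile(pos, c(0.25, 0.75), names = FALSE)
        qs[2] + (rule$k %||% 3) * diff(qs)
      },
      stop_config("unknown outlier rule '%s'", rule$method)
    )
    bad <- !is.na(x) & x > thr
    if (any(bad)) {
      cohort[[f]][bad] <- NA_real_
      log[[length(log) + 1]] <- tibble::tibble(field = f, threshold = thr,
                                               n_removed = sum(bad))
    }
  }
  attr(cohort, "trim_log") <-
    if (length(log)) dplyr::bind_rows(log) else
      tibble::tibble(field = character(), threshold = numeric(),
                     n_removed = integer())
  cohort
}

#' Per-arm summary of one-year costs
#'
#' @param breakdown a [patient_total_cost()] result.
#' @return tibble: `arm`, `n`, `mean_total`, `se_total`.
#' @export
arm_cost_summary <- function(breakdown) {
  dplyr::summarise(dplyr::group_by(breakdown, .data$arm),
                   n = dplyr::n(),
                   mean_total = mean(.data$total),
                   se_total = stats::sd(.data$total) / sqrt(dplyr::n()),
                   .groups = "drop")
}
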