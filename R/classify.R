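#' Classify patients into mutually exclusive health states
#'
#' The decision tree distinguishes two windows. At 30 days a patient is
#' either `DEATH` (death on or before day 30 -- the "at 30 days" endpoint
#' convention makes the boundary inclusive) or `SURVIVOR`. Between 30 days
#' and one year each 30-day survivor occupies exactly one of five states,
#' assigned with strict priority `DEATH > RF > HF > MACE > AS`:
#'
#' * `DEATH` -- died from any cause on or before day 365;
#' * `RF` (renal failure) -- received renal replacement therapy *and*
#'   survived one year (a dialysed patient who dies is `DEATH`);
#' * `HF` (heart failure) -- re-hospitalised for heart failure, not dead
#'   and not in renal failure;
#' * `MACE` -- suffered a myocardial infarction, stroke or (urgent or
#'   staged) revascularisation and none of the higher-priority outcomes;
#' * `AS` (alive and stable) -- the residual state.
#'
#' With `mace_longterm = TRUE` only urgent revascularisations, MI and
#' stroke count as MACE: staged revascularisations performed as part of the
#' culprit-only strategy are protocol-driven rather than adverse, and the
#' long-term MACE utility is re-estimated without them. Patients whose only
#' events are staged revascularisations then fall through to `AS`.
#'
#' @param cohort cohort tibble with columns `death_time`,
#'   `renal_replacement`, `hf_time`, `mace_events`.
#' @param mace_longterm logical; restrict MACE to urgent
#'   revascularisation / MI / stroke.
#' @return `classify_30d()`: character vector `DEATH` / `SURVIVOR`.
#'   `classify_1y()`: character vector over the five states (errors if any
#'   row died within 30 days). `classify_states()`: the cohort with
#'   `state_30d`, `state_1y` (`NA` for 30-day deaths) and `state_1y_lt`
#'   (long-term MACE redefinition) columns added.
#' @export
classify_30d <- function(cohort) {
  ifelse(!is.na(cohort$death_time) & cohort$death_time <= 30,
         "DEATH", "SURVIVOR")
}

#' @rdname classify_30d
#' @export
classify_1y <- function(cohort, mace_longterm = FALSE) {
  if (any(!is.na(cohort$death_time) & cohort$death_time <= 30)) {
    stop("classify_1y() requires 30-day survivors; classify_states() handles full cohorts",
         call. = FALSE)
  }
  dead <- !is.na(cohort$death_time) & cohort$death_time <= 365
  rf <- !dead & cohort$renal_replacement
  hf <- !dead & !rf & !is.na(cohort$hf_time) & cohort$hf_time <= 365
  mace_types <- c("MI", "stroke", "urgent_revasc",
                  if (!mace_longterm) "staged_revasc")
  mace <- !dead & !rf & !hf & has_mace_event(cohort$mace_events, mace_types)
  dplyr::case_when(dead ~ "DEATH", rf ~ "RF", hf ~ "HF", mace ~ "MACE",
                   TRUE ~ "AS")
}

#' @rdname classify_30d
#' @export
classify_states <- function(cohort) {
  cohort$state_30d <- classify_30d(cohort)
  surv <- cohort$state_30d == "SURVIVOR"
  cohort$state_1y <- NA_character_
  cohort$state_1y[surv] <- classify_1y(cohort[surv, ])
  cohort$state_1y_lt <- NA_character_
  cohort$state_1y_lt[surv] <- classify_1y(cohort[surv, ], mace_longterm = TRUE)
  cohort
}

# does a serialized "type:day;type:day" event string contain any of `types`?
has_mace_event <- function(events, types) {
  vapply(strsplit(ifelse(is.na(events), "", events), ";", fixed = TRUE),
         function(tok) {
           tok <- tok[nzchar(tok)]
           any(sub(":.*$", "", tok) %in% types)
         }, logical(1))
}

# state while at risk used by the long-term death model: the 1-year state
# for survivors, the state held at death for decedents (events before the
# death day decide it; renal therapy counts from its start day)
interim_state <- function(cohort) {
  t_end <- ifelse(is.na(cohort$death_time), 365, cohort$death_time)
  dead <- !is.na(cohort$death_time) & cohort$death_time <= 365
  rf_at <- cohort$renal_replacement &
    (!dead | (!is.na(cohort$rrt_day) & cohort$rrt_day <= t_end))
  hf_at <- !is.na(cohort$hf_time) & cohort$hf_time <= t_end
  mace_at <- first_mace_day(cohort$mace_events) <= t_end
  out <- ifelse(rf_at, "RF",
                ifelse(hf_at, "HF", ifelse(mace_at, "MACE", "AS")))
  surv <- is.na(cohort$death_time) | cohort$death_time > 30
  out[!surv] <- "AS"
  out
}

first_mace_day <- function(events) {
  vapply(strsplit(ifelse(is.na(events), "", events), ";", fixed = TRUE),
         function(tok) {
           tok <- tok[nzchar(tok)]
           if (!length(tok)) return(Inf)
           min(as.numeric(sub("^.*:", "", tok)))
         }, numeric(1))
}
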