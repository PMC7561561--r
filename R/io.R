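#' Read and write pipeline inputs and outputs as plain text
#'
#' Cohorts, unit-cost tables and life tables round-trip through CSV;
#' MACE events stay in their semicolon-joined `type:day` serialisation, so
#' the files are self-contained. Fitted parameter sets are serialised to
#' JSON (family, coefficients, information criteria) via \pkg{jsonlite}.
#'
#' @param cohort,path,table,fit arguments of the obvious types.
#' @name io
NULL

#' @rdname io
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname io
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  raw$mace_events[is.na(raw$mace_events)] <- ""
  raw$arm <- factor(raw$arm, .arms)
  raw$age_group <- factor(raw$age_group, c("<50", "50-75", ">75"))
  raw$bmi_class <- factor(raw$bmi_class, c("normal_under", "overweight", "obese"))
  raw$return_to_work <- factor(raw$return_to_work,
                               c("none", "unpaid", "reduced_hours", "full"))
  tibble::as_tibble(raw)
}

#' @rdname io
#' @export
write_unit_costs <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_unit_costs <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname io
#' @export
read_life_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname io
#' @export
write_survival_fit <- function(fit, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to serialise fits", call. = FALSE)
  }
  res <- fit$fit$res
  obj <- list(event = fit$event, family = fit$family,
              window = fit$window,
              coefficients = as.list(stats::setNames(res[, "est"], rownames(res))),
              se = as.list(stats::setNames(res[, "se"], rownames(res))),
              ic = fit$ic)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
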