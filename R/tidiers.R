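#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Broom-style tidiers
#'
#' `tidy()` returns one row per estimated quantity, `glance()` a one-row
#' model summary, for the package's fitted objects: decision-tree
#' parameters, parametric survival fits, panel models, PSA results.
#'
#' @param x a fitted object.
#' @param ... unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy tree_params
#' @export
tidy.tree_params <- function(x, ...) {
  probs <- purrr::map(.arms, function(a) {
    pr <- tree_arm_probs(x, a)
    tibble::tibble(arm = a,
                   endpoint = c("death_30d", names(pr$conditional)),
                   estimate = c(pr$p_death_30d, unname(pr$conditional)))
  })
  dplyr::left_join(dplyr::bind_rows(probs),
                   dplyr::rename(x$rr, rr = "rr"),
                   by = "endpoint")
}

#' @rdname tidiers
#' @method glance tree_params
#' @export
glance.tree_params <- function(x, ...) {
  tibble::tibble(n_co = x$n[["CO-PCI"]], n_mv = x$n[["MV-PCI"]],
                 p_death_30d_co = x$p_death_30d[["CO-PCI"]],
                 p_death_30d_mv = x$p_death_30d[["MV-PCI"]])
}

#' @rdname tidiers
#' @method tidy survival_fit
#' @export
tidy.survival_fit <- function(x, ...) {
  res <- x$fit$res
  tibble::tibble(term = rownames(res), estimate = res[, "est"],
                 conf.low = res[, "L95%"], conf.high = res[, "U95%"],
                 std.error = res[, "se"])
}

#' @rdname tidiers
#' @method glance survival_fit
#' @export
glance.survival_fit <- function(x, ...) {
  best <- x$ic[x$ic$family == x$family, ]
  tibble::tibble(event = x$event, family = x$family, npar = best$npar,
                 logLik = best$logLik, AIC = best$AIC, BIC = best$BIC)
}

#' @rdname tidiers
#' @method tidy panel_model
#' @export
tidy.panel_model <- function(x, ...) {
  coef_table(x)
}

#' @rdname tidiers
#' @method glance panel_model
#' @export
glance.panel_model <- function(x, ...) {
  vc <- lme4::VarCorr(x$fit)
  tibble::tibble(response = x$response, n_patients = x$n_patients,
                 n_obs = x$n_obs,
                 sd_between = attr(vc$id, "stddev")[[1]],
                 sd_residual = attr(vc, "sc"))
}

#' @rdname tidiers
#' @method glance psa_result
#' @export
glance.psa_result <- function(x, ...) {
  inc <- psa_increments(x, effect = intersect(c("qaly", "effect"),
                                              names(x$draws))[1])
  tibble::tibble(n_draws = x$n_draws,
                 mean_delta_cost = mean(inc$delta_cost),
                 mean_delta_effect = mean(inc$delta_effect),
                 ci_cost_low = stats::quantile(inc$delta_cost, 0.025, names = FALSE),
                 ci_cost_high = stats::quantile(inc$delta_cost, 0.975, names = FALSE),
                 ci_effect_low = stats::quantile(inc$delta_effect, 0.025, names = FALSE),
                 ci_effect_high = stats::quantile(inc$delta_effect, 0.975, names = FALSE))
}
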