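#' Incremental cost-effectiveness ratio with dominance labels
#'
#' `delta_cost / delta_effect` when the comparison buys health
#' (`delta_effect > 0`); dominance labels replace the ratio when the signs
#' make it meaningless: `"dominates"` when the new strategy is at least as
#' cheap and at least as effective (strictly better in one), `"dominated"`
#' for the mirror case, `"equivalent"` at exactly (0, 0), `"undefined"`
#' when `delta_effect` is zero. In the south-west quadrant (cheaper, less
#' effective) the ratio is returned as savings per unit of effect forgone.
#'
#' @param delta_cost,delta_effect increments, new strategy minus comparator.
#' @return tibble: `delta_cost`, `delta_effect`, `icer` (`NA` when a label
#'   applies), `label`.
#' @export
compute_icer <- function(delta_cost, delta_effect) {
  label <- dplyr::case_when(
    delta_cost == 0 & delta_effect == 0 ~ "equivalent",
    delta_effect > 0 & delta_cost <= 0 ~ "dominates",
    delta_effect < 0 & delta_cost >= 0 ~ "dominated",
    delta_effect == 0 ~ "undefined",
    TRUE ~ "icer"
  )
  tibble::tibble(
    delta_cost = delta_cost, delta_effect = delta_effect,
    icer = ifelse(label == "icer", delta_cost / delta_effect, NA_real_),
    label = label
  )
}

#' Net monetary benefit
#'
#' `lambda * effect - cost` at willingness-to-pay `lambda` per effect unit.
#'
#' @param cost,effect per-strategy (or incremental) cost and effect.
#' @param lambda monetary value of one effect unit (>= 0).
#' @export
net_monetary_benefit <- function(cost, effect, lambda) {
  if (any(lambda < 0)) stop("lambda must be non-negative", call. = FALSE)
  lambda * effect - cost
}

# ---- parameter distributions for the probabilistic sensitivity analysis ----

#' Declare an uncertain parameter
#'
#' Building blocks of an `uncertainty_spec` for [run_psa()], following the
#' conventional distribution choices: Beta for absolute risks (from event
#' counts, or moment-matched from mean and SE), lognormal for relative
#' risks and hazard multipliers, gamma for costs, Beta on a shifted scale
#' for incremental utilities. A zero SE collapses any distribution to its
#' point value. Beta moment matching that is infeasible (SE too large for
#' the mean) falls back to a logit-normal with a warning.
#'
#' @param name parameter name.
#' @param events,n event count and sample size (`psa_beta_counts`).
#' @param mean,se first two moments on the natural scale.
#' @param meanlog,selog location and scale of a lognormal.
#' @param lower,upper support of the shifted Beta.
#' @param value fixed value (`psa_fixed`).
#' @return one-row tibble (rows are stacked into an `uncertainty_spec`).
#' @name psa_distributions
NULL

#' @rdname psa_distributions
#' @export
psa_beta_counts <- function(name, events, n) {
  tibble::tibble(name = name, dist = "beta_counts", p1 = events, p2 = n)
}

#' @rdname psa_distributions
#' @export
psa_beta <- function(name, mean, se) {
  tibble::tibble(name = name, dist = "beta", p1 = mean, p2 = se)
}

#' @rdname psa_distributions
#' @export
psa_beta_shifted <- function(name, mean, se, lower = -0.5, upper = 0.5) {
  tibble::tibble(name = name, dist = "beta_shifted", p1 = mean, p2 = se,
                 p3 = lower, p4 = upper)
}

#' @rdname psa_distributions
#' @export
psa_lognormal <- function(name, meanlog, selog) {
  tibble::tibble(name = name, dist = "lognormal", p1 = meanlog, p2 = selog)
}

#' @rdname psa_distributions
#' @export
psa_gamma <- function(name, mean, se) {
  tibble::tibble(name = name, dist = "gamma", p1 = mean, p2 = se)
}

#' @rdname psa_distributions
#' @export
psa_normal <- function(name, mean, se) {
  tibble::tibble(name = name, dist = "normal", p1 = mean, p2 = se)
}

#' @rdname psa_distributions
#' @export
psa_fixed <- function(name, value) {
  tibble::tibble(name = name, dist = "fixed", p1 = value, p2 = 0)
}

beta_moments <- function(mean, se) {
  v <- se^2
  vmax <- mean * (1 - mean)
  if (v >= vmax) return(NULL)
  k <- vmax / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

draw_param <- function(row, n) {
  # scalars extracted from coefficient tables may carry names that would
  # corrupt downstream name-based indexing
  for (k in intersect(c("p1", "p2", "p3", "p4"), names(row))) {
    row[[k]] <- unname(row[[k]])
  }
  se0 <- function(point, draw) if (isTRUE(row$p2 == 0)) rep(point, n) else draw
  switch(row$dist,
    fixed = rep(row$p1, n),
    beta_counts = stats::rbeta(n, row$p1, row$p2 - row$p1),
    beta = {
      m <- beta_moments(row$p1, row$p2)
      if (is.null(m) && row$p2 > 0) {
        warning(sprintf("beta moment matching infeasible for '%s'; using logit-normal",
                        row$name), call. = FALSE)
        se0(row$p1, stats::plogis(stats::rnorm(n, stats::qlogis(row$p1),
                                               row$p2 / (row$p1 * (1 - row$p1)))))
      } else {
        se0(row$p1, stats::rbeta(n, m["shape1"], m["shape2"]))
      }
    },
    beta_shifted = {
      width <- row$p4 - row$p3
      m01 <- (row$p1 - row$p3) / width
      m <- beta_moments(m01, row$p2 / width)
      if (is.null(m) && row$p2 > 0) {
        warning(sprintf("beta moment matching infeasible for '%s'; using logit-normal",
                        row$name), call. = FALSE)
        x <- stats::plogis(stats::rnorm(n, stats::qlogis(m01),
                                        (row$p2 / width) / (m01 * (1 - m01))))
        se0(row$p1, row$p3 + width * x)
      } else {
        se0(row$p1, row$p3 + width * stats::rbeta(n, m["shape1"], m["shape2"]))
      }
    },
    lognormal = se0(exp(row$p1), stats::rlnorm(n, row$p1, row$p2)),
    gamma = {
      if (row$p1 <= 0) rep(row$p1, n) else {
        shape <- (row$p1 / row$p2)^2
        se0(row$p1, stats::rgamma(n, shape = shape, scale = row$p1 / shape))
      }
    },
    normal = se0(row$p1, stats::rnorm(n, row$p1, row$p2)),
    stop_config("unknown PSA distribution '%s'", row$dist)
  )
}

#' Collapse an uncertainty specification to its point values
#'
#' Every parameter becomes a `fixed` entry at the mean of its declared
#' distribution (event-count Betas at `events / n`, lognormals at their
#' mean). A PSA over the result reproduces the deterministic evaluation
#' exactly, which is the standard degeneracy check of a Monte-Carlo
#' propagation.
#'
#' @param uncertainty_spec tibble of stacked [psa_distributions] rows.
#' @return tibble of `fixed` rows with the same parameter names.
#' @export
degenerate_uncertainty <- function(uncertainty_spec) {
  point <- vapply(seq_len(nrow(uncertainty_spec)), function(i) {
    row <- uncertainty_spec[i, ]
    switch(row$dist,
      beta_counts = row$p1 / row$p2,
      lognormal = exp(row$p1 + row$p2^2 / 2),
      row$p1)
  }, numeric(1))
  dplyr::bind_rows(purrr::map2(uncertainty_spec$name, point, psa_fixed))
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: each uncertain
#' parameter is drawn independently from its declared distribution, the
#' model is evaluated per draw, and the per-draw results are returned for
#' summarising into intervals, acceptability curves and the
#' cost-effectiveness plane. With every SE zero, all draws equal the
#' deterministic point estimate. Reproducible given `seed`.
#'
#' @param uncertainty_spec tibble of stacked [psa_distributions] rows.
#' @param model_fn `function(theta)` taking one named parameter list and
#'   returning a data frame with an `arm` column and result columns
#'   (typically `cost` and `effect`).
#' @param n_draws number of Monte-Carlo draws.
#' @param seed RNG seed.
#' @return object of class `psa_result`: `$draws` (model outputs with a
#'   `draw` column), `$params` (the drawn parameter values), `$n_draws`.
#' @export
run_psa <- function(uncertainty_spec, model_fn, n_draws = 10000, seed = NULL) {
  stopifnot(nrow(uncertainty_spec) >= 1, n_draws >= 1)
  if (anyDuplicated(uncertainty_spec$name)) {
    stop_config("duplicated parameter names in uncertainty_spec")
  }
  if (!is.null(seed)) set.seed(seed)
  params <- purrr::map(seq_len(nrow(uncertainty_spec)), function(i) {
    draw_param(uncertainty_spec[i, ], n_draws)
  })
  params <- purrr::map(params, unname)
  names(params) <- uncertainty_spec$name
  params <- tibble::as_tibble(params)
  draws <- purrr::map(seq_len(n_draws), function(d) {
    out <- model_fn(as.list(params[d, ]))
    out$draw <- d
    out
  })
  structure(list(draws = dplyr::bind_rows(draws), params = params,
                 n_draws = n_draws),
            class = "psa_result")
}

#' Incremental draws from a PSA
#'
#' @param psa a [run_psa()] result (draws must have `arm`, `cost` and the
#'   effect column).
#' @param effect column holding the effect.
#' @return tibble: `draw`, `delta_cost`, `delta_effect` (CO-PCI minus
#'   MV-PCI).
#' @export
psa_increments <- function(psa, effect = "effect") {
  d <- psa$draws
  co <- d[d$arm == "CO-PCI", ]
  mv <- d[d$arm == "MV-PCI", ]
  co <- co[order(co$draw), ]; mv <- mv[order(mv$draw), ]
  tibble::tibble(draw = co$draw,
                 delta_cost = co$cost - mv$cost,
                 delta_effect = co[[effect]] - mv[[effect]])
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of draws in which each
#' strategy has the higher net monetary benefit; exact ties are split
#' equally. Probabilities sum to 1 across strategies at every threshold.
#'
#' @param increments a [psa_increments()] tibble (CO-PCI vs. MV-PCI).
#' @param lambda_grid thresholds in euro per effect unit; the default spans
#'   0-100,000 in 500-euro steps.
#' @return tibble of class `ceac_curve`: `lambda`, `strategy`,
#'   `probability`.
#' @export
build_ceac <- function(increments, lambda_grid = seq(0, 1e5, by = 500)) {
  if (nrow(increments) == 0) stop_config("no PSA draws")
  probs <- vapply(lambda_grid, function(l) {
    nmb <- net_monetary_benefit(increments$delta_cost,
                                increments$delta_effect, l)
    mean((nmb > 0) + 0.5 * (nmb == 0))
  }, numeric(1))
  out <- tibble::tibble(
    lambda = rep(lambda_grid, 2),
    strategy = rep(.arms, each = length(lambda_grid)),
    probability = c(probs, 1 - probs)
  )
  class(out) <- c("ceac_curve", class(out))
  out
}

#' Cost-effectiveness plane quadrant summary
#'
#' Fractions of PSA draws in each quadrant of the incremental
#' cost-effectiveness plane (boundary draws are assigned to the
#' more-effective / more-costly side they touch, i.e. by `>= 0` on both
#' axes); fractions sum to 1.
#'
#' @param increments a [psa_increments()] tibble.
#' @return tibble: `quadrant`, `delta_effect_sign`, `delta_cost_sign`,
#'   `fraction`.
#' @export
build_cep <- function(increments) {
  if (nrow(increments) == 0) stop_config("no PSA draws")
  de <- increments$delta_effect >= 0
  dc <- increments$delta_cost >= 0
  tibble::tibble(
    quadrant = c("upper_right", "upper_left", "lower_left", "lower_right"),
    delta_effect_sign = c("+", "-", "-", "+"),
    delta_cost_sign = c("+", "+", "-", "-"),
    fraction = c(mean(de & dc), mean(!de & dc), mean(!de & !dc),
                 mean(de & !dc))
  )
}
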