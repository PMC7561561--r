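#' Pre-specified subgroup analyses
#'
#' Re-runs the lifelong evaluation for the protocol subgroups (age groups,
#' sex, diabetes status) under the adaptation rules of the economic
#' protocol: the treatment effect (relative risks, including the 30-day
#' mortality ratio) estimated on the whole sample is applied to
#' subgroup-specific MV-PCI baseline probabilities; health utilities are
#' re-centred to the subgroup's alive-and-stable average (via the fitted
#' covariate model) with the absolute state offsets shared across
#' subgroups; one-year costs and monthly state costs are recomputed from
#' subgroup data; survival covariates take the subgroup's values through
#' its covariate mixture. A subgroup with an empty arm is skipped with a
#' warning.
#'
#' @param pl a fitted [cua_pipeline()].
#' @param groups named list of predicate functions over the cohort; the
#'   default is the protocol set (`age<50`, `age 50-75`, `age>75`,
#'   female, male, no diabetes, diabetes).
#' @return tibble: per subgroup and arm, `n`, lifelong `cost` and `qaly`,
#'   plus increments, `icer` and dominance `label` on the CO-PCI rows.
#' @export
subgroup_analysis <- function(pl, groups = protocol_subgroups()) {
  purrr::imap(groups, function(pred, nm) {
    sub <- pl$cohort[pred(pl$cohort), ]
    n_arm <- table(factor(sub$arm, .arms))
    if (any(n_arm == 0)) {
      warning(sprintf("subgroup '%s' has an empty arm; skipped", nm),
              call. = FALSE)
      return(NULL)
    }
    res <- subgroup_evaluation(pl, sub)
    dc <- res$cost[res$arm == "CO-PCI"] - res$cost[res$arm == "MV-PCI"]
    de <- res$qaly[res$arm == "CO-PCI"] - res$qaly[res$arm == "MV-PCI"]
    ic <- compute_icer(dc, de)
    tibble::tibble(subgroup = nm, arm = res$arm,
                   n = as.integer(n_arm[res$arm]),
                   cost = res$cost, qaly = res$qaly,
                   delta_cost = ifelse(res$arm == "CO-PCI", dc, NA),
                   delta_qaly = ifelse(res$arm == "CO-PCI", de, NA),
                   icer = ifelse(res$arm == "CO-PCI", ic$icer, NA),
                   label = ifelse(res$arm == "CO-PCI", ic$label, NA))
  }) |>
    purrr::compact() |>
    dplyr::bind_rows()
}

#' @rdname subgroup_analysis
#' @export
protocol_subgroups <- function() {
  list(
    "age<50" = function(d) d$age_group == "<50",
    "age 50-75" = function(d) d$age_group == "50-75",
    "age>75" = function(d) d$age_group == ">75",
    "female" = function(d) !d$male,
    "male" = function(d) d$male,
    "no diabetes" = function(d) !d$diabetes,
    "diabetes" = function(d) d$diabetes
  )
}

# lifelong evaluation of one subgroup under the adaptation rules
subgroup_evaluation <- function(pl, sub) {
  sub_tree <- estimate_tree_probabilities(sub)
  # subgroup MV-PCI baseline, whole-sample treatment effect
  tree <- sub_tree
  tree$rr <- pl$tree$rr
  rr30 <- pl$tree$rr$rr[pl$tree$rr$endpoint == "death_30d"]
  tree$p_death_30d[["CO-PCI"]] <- min(1, tree$p_death_30d[["MV-PCI"]] * rr30)

  breakdown <- pl$breakdown[pl$breakdown$id %in% sub$id, ]
  ac <- arm_cost_summary(breakdown)
  year1_costs <- stats::setNames(ac$mean_total, ac$arm)[.arms]

  u30 <- vapply(.arms, function(a) {
    mean(sub$eq5d_30d[sub$arm == a], na.rm = TRUE)
  }, numeric(1))
  utilities <- list(u30 = u30,
                    state = state_values_marginal(pl$utility_model, sub))
  markov <- pl$markov
  markov$utilities <- state_values_marginal(pl$utility_model_lt, sub)
  markov$costs_monthly <- state_values_marginal(pl$cost_model, sub) / 6
  lifelong_evaluation(tree, utilities, year1_costs, markov,
                      covariate_mix(sub), pl$discount, pl$horizon_age)
}
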