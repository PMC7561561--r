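ref_tree <- function() {
  cnt <- ref_tree_counts()
  tree_params(n = cnt$n, deaths_30d = cnt$deaths_30d,
              conditional = cnt$conditional)
}

flat_utilities <- function(u = 1) {
  list(u30 = c("CO-PCI" = u, "MV-PCI" = u),
       state = c(AS = u, HF = u, MACE = u, RF = u))
}

test_that("decision tree degenerate cases have closed forms", {
  cnt <- ref_tree_counts()
  all_death <- suppressWarnings(tree_params(
    n = c("CO-PCI" = 10, "MV-PCI" = 10),
    deaths_30d = c("CO-PCI" = 10, "MV-PCI" = 10),
    conditional = dplyr::mutate(cnt$conditional, `CO-PCI` = c(1, 0, 0, 0, 0) * 0,
                                `MV-PCI` = c(1, 0, 0, 0, 0) * 0)))
  res <- suppressWarnings(run_decision_tree(all_death, flat_utilities(0.7),
                                            c("CO-PCI" = 0, "MV-PCI" = 0)))
  # only the half-month pre-death contribution remains
  expect_equal(res$qaly, rep(0.5 * (1 / 12) * 0.7, 2))

  no_death <- suppressWarnings(tree_params(
    n = c("CO-PCI" = 10, "MV-PCI" = 10),
    deaths_30d = c("CO-PCI" = 0, "MV-PCI" = 0),
    conditional = dplyr::mutate(cnt$conditional, `CO-PCI` = c(0, 0, 0, 0, 10),
                                `MV-PCI` = c(0, 0, 0, 0, 10))))
  res <- suppressWarnings(run_decision_tree(no_death, flat_utilities(1),
                                            c("CO-PCI" = 0, "MV-PCI" = 0)))
  # a full year in full health
  expect_equal(res$qaly, c(1, 1))
})

test_that("the mortality schedule scales with the life table", {
  flat <- tibble::tibble(age = 60:80, annual_death_prob = 0.02)
  expect_equal(build_mortality_schedule(0.01, flat, 65, 36), rep(0.01, 36))

  doubling <- tibble::tibble(age = c(65, 66, 67),
                             annual_death_prob = c(0.02, 0.04, 0.08))
  sched <- build_mortality_schedule(0.3, doubling, 65, 30)
  expect_equal(sched[1:12], rep(0.3, 12))
  expect_equal(sched[13:24], rep(0.6, 12))
  expect_equal(sched[25:30], rep(1, 6))  # capped at certainty

  # brute-force elementwise oracle on a 10-row toy table
  toy <- tibble::tibble(age = 70:79,
                        annual_death_prob = seq(0.03, 0.12, by = 0.01))
  horizon <- 60
  sched <- build_mortality_schedule(0.02, toy, 70, horizon)
  manual <- vapply(seq_len(horizon), function(c) {
    age <- 70 + (c - 1) %/% 12
    min(1, 0.02 * toy$annual_death_prob[toy$age == min(age, 79)] / 0.03)
  }, numeric(1))
  expect_equal(sched, manual)

  expect_error(build_mortality_schedule(0.01,
                                        tibble::tibble(age = 60,
                                                       annual_death_prob = 0),
                                        60, 5), "zero")
})

test_that("a hazard-free cohort accrues the discounted geometric annuity", {
  u <- 0.8
  spec <- markov_spec(p_death = 0, utilities = c(AS = u, RF = 0, HF = 0, MACE = 0),
                      discount = 0.03, horizon = 12 * 30)
  trace <- run_markov(spec, c(AS = 1, RF = 0, HF = 0, MACE = 0, DEATH = 0))
  closed <- u / 12 * sum(1.03^(-(1:(12 * 30)) / 12))
  expect_equal(trace$cum_qaly[nrow(trace)], closed, tolerance = 1e-8)
  # zero discounting accrues at least as much
  spec0 <- markov_spec(p_death = 0, utilities = c(AS = u, RF = 0, HF = 0, MACE = 0),
                       discount = 0, horizon = 12 * 30)
  trace0 <- run_markov(spec0, c(AS = 1, RF = 0, HF = 0, MACE = 0, DEATH = 0))
  expect_gt(trace0$cum_qaly[nrow(trace0)], trace$cum_qaly[nrow(trace)])
})

test_that("certain first-cycle death terminates the cohort with no payoff", {
  spec <- markov_spec(p_death = 1, utilities = c(AS = 1, RF = 1, HF = 1, MACE = 1),
                      costs_monthly = c(AS = 100, RF = 0, HF = 0, MACE = 0),
                      horizon = 100)
  trace <- run_markov(spec, c(AS = 1, RF = 0, HF = 0, MACE = 0, DEATH = 0))
  expect_equal(nrow(trace), 1)
  expect_equal(trace$cum_qaly, 0)
  expect_equal(trace$cum_cost, 0)
  expect_equal(trace$DEATH, 1)
})

test_that("occupancy stays a distribution and death mass is monotone", {
  set.seed(9)
  spec <- markov_spec(p_death = matrix(runif(240, 0, 0.05), 60, 4),
                      p_hf = 0.01, p_mace = 0.02, p_rf = 0.005,
                      utilities = c(AS = 0.8, RF = 0.6, HF = 0.55, MACE = 0.75),
                      costs_monthly = c(AS = 50, RF = 300, HF = 500, MACE = 120),
                      horizon = 60)
  trace <- run_markov(spec, c(AS = 0.7, RF = 0.1, HF = 0.1, MACE = 0.1,
                              DEATH = 0))
  occ <- trace[, c("AS", "RF", "HF", "MACE", "DEATH")]
  expect_true(all(abs(rowSums(occ) - 1) < 1e-10))
  expect_true(all(diff(trace$DEATH) >= -1e-12))
  expect_true(all(diff(trace$cum_qaly) >= 0))
})

test_that("MACE survivors reset to alive-and-stable in one cycle", {
  spec <- markov_spec(p_death = 0, p_mace = 0,
                      utilities = c(AS = 1, RF = 1, HF = 1, MACE = 1),
                      horizon = 3)
  trace <- run_markov(spec, c(AS = 0, RF = 0, HF = 0, MACE = 1, DEATH = 0))
  expect_equal(trace$AS[1], 1)
  expect_equal(trace$MACE[1], 0)
})

test_that("the cohort engine agrees with a micro-simulation oracle", {
  # 3-state toy chain (AS, MACE, DEATH embedded in the 5-state structure)
  p_d <- 0.01; p_m <- 0.03
  spec <- markov_spec(p_death = p_d, p_hf = 0, p_mace = p_m,
                      utilities = c(AS = 0.9, RF = 0, HF = 0, MACE = 0.7),
                      costs_monthly = c(AS = 20, RF = 0, HF = 0, MACE = 400),
                      discount = 0.03, horizon = 120)
  trace <- run_markov(spec, c(AS = 1, RF = 0, HF = 0, MACE = 0, DEATH = 0))

  set.seed(11)
  walkers <- 100000
  state <- rep(1L, walkers)  # 1 AS, 2 MACE, 3 DEATH
  qaly <- cost <- 0
  qalys <- costs <- numeric(walkers)
  for (cyc in 1:120) {
    u <- stats::runif(walkers)
    new <- state
    as_ <- state == 1L
    new[as_ & u < p_d] <- 3L
    new[as_ & u >= p_d & u < p_d + p_m] <- 2L
    mc <- state == 2L
    new[mc & u < p_d] <- 3L
    new[mc & u >= p_d & u < p_d + p_m] <- 2L
    new[mc & u >= p_d + p_m] <- 1L
    state <- new
    df <- 1.03^(-cyc / 12)
    qalys <- qalys + c(0.9, 0.7, 0)[state] / 12 * df
    costs <- costs + c(20, 400, 0)[state] * df
    if (all(state == 3L)) break
  }
  mc_q <- mean(qalys); se_q <- stats::sd(qalys) / sqrt(walkers)
  mc_c <- mean(costs); se_c <- stats::sd(costs) / sqrt(walkers)
  expect_lt(abs(trace$cum_qaly[nrow(trace)] - mc_q), 3 * se_q)
  expect_lt(abs(trace$cum_cost[nrow(trace)] - mc_c), 3 * se_c)
})

test_that("the batch engine reproduces run_markov exactly", {
  set.seed(13)
  H <- 80
  d <- matrix(runif(H * 4, 0, 0.04), H, 4)
  p_hf <- runif(H, 0, 0.02); p_mace <- runif(H, 0, 0.03)
  u <- c(AS = 0.85, RF = 0.6, HF = 0.5, MACE = 0.7)
  cm <- c(AS = 10, RF = 200, HF = 350, MACE = 90)
  spec <- markov_spec(p_death = d, p_hf = p_hf, p_mace = p_mace,
                      utilities = u, costs_monthly = cm, discount = 0.03,
                      horizon = H)
  start <- c(AS = 0.6, RF = 0.15, HF = 0.1, MACE = 0.15, DEATH = 0)
  trace <- run_markov(spec, start)
  batch <- shockcea:::markov_batch(
    d_as = d[, 1, drop = FALSE], d_rf = d[, 2, drop = FALSE],
    d_hf = d[, 3, drop = FALSE], d_mace = d[, 4, drop = FALSE],
    p_hf = matrix(p_hf), p_mace = matrix(p_mace), p_rf = matrix(0, H, 1),
    util = matrix(c(u[["AS"]], u[["RF"]], u[["HF"]], u[["MACE"]]), 1),
    cost_m = matrix(c(cm[["AS"]], cm[["RF"]], cm[["HF"]], cm[["MACE"]]), 1),
    discount = 0.03, start = matrix(start[1:4], 1))
  expect_equal(batch$qaly, trace$cum_qaly[nrow(trace)], tolerance = 1e-12)
  expect_equal(batch$cost, trace$cum_cost[nrow(trace)], tolerance = 1e-12)
})

test_that("invalid transition matrices are rejected", {
  bad <- diag(5) * 1.5
  spec <- list(states = c("AS", "RF", "HF", "MACE", "DEATH"),
               transitions = bad,
               utilities = stats::setNames(rep(1, 5), c("AS", "RF", "HF", "MACE", "DEATH")),
               costs_monthly = stats::setNames(rep(0, 5), c("AS", "RF", "HF", "MACE", "DEATH")),
               discount = 0, horizon = 5)
  expect_error(run_markov(spec, c(AS = 1, RF = 0, HF = 0, MACE = 0, DEATH = 0)),
               "sum to 1")
})

test_that("lifelong evaluation decomposes into tree plus annuity when hazard-free", {
  tree <- ref_tree()
  u <- flat_utilities(0.8)
  zero_h <- arm_hazards(parametric_hazard("exponential", rate = 0),
                        parametric_hazard("exponential", rate = 0))
  markov <- list(death_fit = zero_h, hf_fit = zero_h, mace_fit = zero_h,
                 life_table = synthetic_life_table(),
                 utilities = u$state,
                 costs_monthly = c(AS = 0, RF = 0, HF = 0, MACE = 0), p_rf = 0)
  mix <- tibble::tibble(age_group = factor("50-75", c("<50", "50-75", ">75")),
                        male = TRUE, diabetes = FALSE, weight = 1,
                        start_age = 70)
  year1 <- run_decision_tree(tree, u, c("CO-PCI" = 1000, "MV-PCI" = 1000))
  ll <- lifelong_evaluation(tree, u, c("CO-PCI" = 1000, "MV-PCI" = 1000),
                            markov, mix, discount = 0.03, horizon_age = 100)
  horizon <- (100 - 70) * 12
  annuity <- 0.8 / 12 * sum(1.03^(-(1:horizon) / 12)) * 1.03^(-1)
  for (a in c("CO-PCI", "MV-PCI")) {
    pr <- tree_arm_probs(tree, a)
    alive <- (1 - pr$p_death_30d) * (1 - pr$conditional[["death"]])
    expect_equal(ll$qaly[ll$arm == a],
                 year1$qaly[year1$arm == a] + alive * annuity,
                 tolerance = 1e-8)
    expect_gte(ll$qaly[ll$arm == a], year1$qaly[year1$arm == a])
    expect_equal(ll$cost[ll$arm == a], 1000)
  }
})
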