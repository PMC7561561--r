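test_that("ICERs and dominance labels cover every sign combination", {
  expect_equal(compute_icer(841, 0.0933)$icer, 841 / 0.0933)
  expect_equal(compute_icer(-226, 0.203)$label, "dominates")
  expect_equal(compute_icer(500, -0.1)$label, "dominated")
  expect_equal(compute_icer(0, 0)$label, "equivalent")
  expect_equal(compute_icer(500, 0)$label, "undefined")
  sw <- compute_icer(-500, -0.1)
  expect_equal(sw$label, "icer")
  expect_equal(sw$icer, 5000)
  # identity: icer * delta_effect returns delta_cost
  ic <- compute_icer(1234.5, 0.321)
  expect_equal(ic$icer * ic$delta_effect, ic$delta_cost, tolerance = 1e-9)
})

test_that("net monetary benefit is linear and vanishes at the ICER", {
  expect_equal(net_monetary_benefit(500, 2, 0), -500)
  expect_equal(net_monetary_benefit(2060, 0.293, 30000),
               30000 * 0.293 - 2060)
  de <- 0.0577; dc <- 841
  lambda_star <- dc / de
  expect_equal(net_monetary_benefit(dc, de, lambda_star), 0, tolerance = 1e-9)
  expect_error(net_monetary_benefit(1, 1, -5), "non-negative")
})

test_that("PSA draws are seed-reproducible and degenerate at zero SE", {
  spec <- dplyr::bind_rows(
    psa_beta_counts("p", 177, 344),
    psa_lognormal("rr", log(0.84), 0.1),
    psa_gamma("cost", 25000, 1400),
    psa_beta("u", 0.76, 0.02),
    psa_beta_shifted("du", -0.05, 0.01),
    psa_normal("z", 3, 1),
    psa_fixed("k", 42)
  )
  model <- function(theta) {
    tibble::tibble(arm = c("CO-PCI", "MV-PCI"),
                   cost = c(theta$cost, theta$cost * theta$rr),
                   effect = c(theta$u, theta$u + theta$du))
  }
  a <- run_psa(spec, model, n_draws = 50, seed = 99)
  b <- run_psa(spec, model, n_draws = 50, seed = 99)
  expect_identical(a$draws, b$draws)
  expect_equal(a$params$k, rep(42, 50))
  # Beta from counts matches the event rate in expectation
  big <- run_psa(spec, model, n_draws = 4000, seed = 1)
  expect_lt(abs(mean(big$params$p) - 177 / 344),
            3 * stats::sd(big$params$p) / sqrt(4000))

  degenerate <- dplyr::bind_rows(
    psa_lognormal("rr", log(0.84), 0),
    psa_gamma("cost", 25000, 0),
    psa_beta("u", 0.76, 0),
    psa_beta_shifted("du", -0.05, 0),
    psa_fixed("k", 1)
  )
  d <- run_psa(degenerate, function(theta) {
    tibble::tibble(arm = "CO-PCI", cost = theta$cost,
                   effect = theta$u + theta$du, rr = theta$rr)
  }, n_draws = 5, seed = 1)
  expect_equal(unique(d$draws$cost), 25000)
  expect_equal(unique(d$draws$effect), 0.76 - 0.05)
  expect_equal(unique(d$draws$rr), 0.84)
})

test_that("infeasible beta moments fall back to logit-normal with a warning", {
  spec <- psa_beta("u", 0.5, 0.6)  # se^2 > m(1-m)
  expect_warning(run_psa(spec, function(theta) {
    tibble::tibble(arm = "CO-PCI", cost = 1, effect = theta$u)
  }, n_draws = 10, seed = 1), "logit-normal")
})

test_that("CEAC splits ties and recognises dominance", {
  same <- tibble::tibble(draw = 1:20, delta_cost = 0, delta_effect = 0)
  ceac <- build_ceac(same, lambda_grid = c(0, 1e4))
  expect_true(all(ceac$probability == 0.5))

  dominant <- tibble::tibble(draw = 1:20, delta_cost = -100,
                             delta_effect = 0.1)
  ceac <- build_ceac(dominant, lambda_grid = c(0, 1e4, 5e4))
  co <- ceac[ceac$strategy == "CO-PCI", ]
  expect_true(all(co$probability == 1))
  # probabilities always sum to one across strategies
  tot <- tapply(ceac$probability, ceac$lambda, sum)
  expect_true(all(abs(tot - 1) < 1e-12))

  # upper-right-quadrant draws give a CEAC rising in lambda
  set.seed(3)
  ur <- tibble::tibble(draw = 1:500,
                       delta_cost = abs(rnorm(500, 800, 300)),
                       delta_effect = abs(rnorm(500, 0.05, 0.02)))
  ceac <- build_ceac(ur, lambda_grid = seq(0, 1e5, 5000))
  co <- ceac[ceac$strategy == "CO-PCI", ]
  expect_true(all(diff(co$probability) >= -1e-12))
})

test_that("CEAC crosses one half near the ICER under symmetric uncertainty", {
  set.seed(5)
  n <- 20000
  dc <- rnorm(n, 800, 50)
  de <- rnorm(n, 0.08, 0.005)
  icer <- 800 / 0.08
  inc <- tibble::tibble(draw = seq_len(n), delta_cost = dc, delta_effect = de)
  ceac <- build_ceac(inc, lambda_grid = icer)
  p <- ceac$probability[ceac$strategy == "CO-PCI"]
  expect_lt(abs(p - 0.5), 0.02)
})

test_that("cost-effectiveness plane fractions sum to one", {
  set.seed(7)
  inc <- tibble::tibble(draw = 1:1000, delta_cost = rnorm(1000),
                        delta_effect = rnorm(1000))
  cep <- build_cep(inc)
  expect_equal(sum(cep$fraction), 1)
  expect_error(build_cep(inc[0, ]), "no PSA draws")
  expect_error(build_ceac(inc[0, ]), "no PSA draws")
})

test_that("plot builders return ggplot objects", {
  inc <- tibble::tibble(draw = 1:50, delta_cost = rnorm(50, 800, 200),
                        delta_effect = rnorm(50, 0.1, 0.05))
  expect_s3_class(plot_cep(inc, lambda = 3e4), "ggplot")
  expect_s3_class(plot_ceac(build_ceac(inc, seq(0, 1e4, 1e3))), "ggplot")
  spec <- markov_spec(p_death = 0.01,
                      utilities = c(AS = 1, RF = 1, HF = 1, MACE = 1),
                      horizon = 24)
  trace <- run_markov(spec, c(AS = 1, RF = 0, HF = 0, MACE = 0, DEATH = 0))
  expect_s3_class(ggplot2::autoplot(trace), "ggplot")
})
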