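# internal helpers shared across modules

# canonical health-state codes, in classification priority order
.states <- c("DEATH", "RF", "HF", "MACE", "AS")
# states a 30-day survivor can occupy at one year (tree endpoints)
.endpoints <- c("death", "renal_failure", "heart_failure", "mace", "as")
# living Markov states
.markov_states <- c("AS", "RF", "HF", "MACE")

.arms <- c("CO-PCI", "MV-PCI")

# days per monthly Markov cycle (365.25 / 12)
CYCLE_DAYS <- 30.4375

# German value-set floor for EQ5D utilities
UTILITY_FLOOR <- -0.205

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_config("`%s` must be a probability in [0, 1]", name)
  }
  invisible(x)
}

assert_prob_vector <- function(p, name, tol = 1e-12) {
  assert_prob(p, name)
  if (abs(sum(p) - 1) > tol) {
    stop_config("`%s` must sum to 1 (got %.15g)", name, sum(p))
  }
  invisible(p)
}

# draw from a gamma distribution parameterised by mean and coefficient of
# variation; mean 0 gives exact zeros
rgamma_mean_cv <- function(n, mean, cv) {
  out <- numeric(n)
  pos <- mean > 1e-12
  if (length(mean) == 1L) pos <- rep(pos, n)
  if (length(mean) == 1L) mean <- rep(mean, n)
  shape <- 1 / cv^2
  out[pos] <- stats::rgamma(sum(pos), shape = shape, scale = mean[pos] / shape)
  out
}

# E[min(X, cap)] for X ~ gamma(mean, cv); closed form via the gamma cdf
egamma_capped <- function(mean, cv, cap) {
  if (mean <= 0) return(0)
  shape <- 1 / cv^2
  rate <- shape / mean
  mean * stats::pgamma(cap, shape + 1, rate) +
    cap * (1 - stats::pgamma(cap, shape, rate))
}

# inverse-cdf draw from an exponential restricted to (lo, hi]
rexp_trunc <- function(n, rate, lo, hi) {
  plo <- stats::pexp(lo, rate)
  phi <- stats::pexp(hi, rate)
  u <- stats::runif(n, plo, phi)
  stats::qexp(u, rate)
}

# signif() that mirrors how results tables are printed (3 significant figures)
signif3 <- function(x) signif(x, 3)
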