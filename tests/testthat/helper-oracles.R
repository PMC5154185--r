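# Independent oracles used across the suite.

# Efron-tie-corrected Cox partial log-likelihood for a single coefficient b
# and covariate vector x (brute-force, follows the textbook definition).
efron_loglik <- function(b, time, event, x) {
  eta <- x * b
  risk <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sumR <- sum(risk[R])
    sumD <- sum(risk[D])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sumR - (l / d) * sumD)
  }
  ll
}

# line-search maximiser of the Efron partial likelihood
efron_grid_mle <- function(time, event, x, lower = -8, upper = 8) {
  optimize(function(b) efron_loglik(b, time, event, x),
           c(lower, upper), maximum = TRUE, tol = 1e-8)$maximum
}

# closed-form chance-policy expectations on an 8-flower maze
chance_oracles <- list(
  total_revisits = 8 * sum(1 / (1:8)) - 8,               # coupon collector
  correct_in_first_eight = 8 * (1 - (7 / 8)^8),          # occupancy
  correct_before_first_revisit = sum(cumprod((8:1) / 8))
)

# deterministic clockwise-cycle transition matrix (row i -> i+1 mod 8)
cycle_matrix <- function(n = 8) {
  P <- matrix(0, n, n)
  for (i in seq_len(n)) P[i, i %% n + 1] <- 1
  P
}

# random visit sequence (not a policy draw; arbitrary ids for metric tests)
random_sequence <- function(len = sample(1:20, 1), n_flowers = 8)
  sample.int(n_flowers, len, replace = TRUE)
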