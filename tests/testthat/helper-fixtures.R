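# Small fixtures built in code.

# tiny fully-specified dataset: 3 samples, 2 features
tiny_dataset <- function() {
  survival_dataset(
    matrix(c(1, 0, 2,
             0, 1, 1), ncol = 2,
           dimnames = list(NULL, c("g1", "g2"))),
    time = c(2, 5, 1), status = c(1, 0, 1)
  )
}

# uncensored simulated dataset (C >= 1 guarantees no censoring)
uncensored_sim <- function(n = 50, m = 8, seed = 1, k = 1) {
  w <- rep(c(1, -1), length.out = m)
  make_dataset(simulation_config(n_train = n, n_test = 20, m = m, r = 0.4,
                                 k = k, w_pattern = w, C = 2, seed = seed))
}

# censored simulated dataset at the default design
censored_sim <- function(n = 60, m = 8, seed = 2) {
  w <- rep(c(1, -1), length.out = m)
  make_dataset(simulation_config(n_train = n, n_test = 20, m = m, r = 0.4,
                                 w_pattern = w, seed = seed))
}

# closed-form kernel ridge dual solution (the no-censoring oracle)
ridge_dual_oracle <- function(k_centered, y_centered, lambda) {
  n <- nrow(k_centered)
  solve(k_centered + n * lambda * diag(n), y_centered)
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
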