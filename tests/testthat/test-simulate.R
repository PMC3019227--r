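test_that("AR covariates have the prescribed correlation structure", {
  x0 <- ar_covariates(2000, 6, 0, seed = 51)
  expect_lt(max(abs(cor(x0)[upper.tri(diag(6))])), 0.1)

  x8 <- ar_covariates(2000, 6, 0.8, seed = 52)
  adj <- sapply(1:5, function(j) cor(x8[, j], x8[, j + 1]))
  expect_true(all(adj > 0.75 & adj < 0.85))

  for (r in c(0.3, 0.6)) {
    x <- ar_covariates(2000, 4, r, seed = 53)
    expect_lt(abs(cor(x[, 1], x[, 3]) - r^2), 0.05)
  }
  expect_error(ar_covariates(10, 3, 1), class = "kernaft_error_input")
})

test_that("empirical covariance converges to r^|i-j|", {
  r <- 0.4
  x <- ar_covariates(20000, 12, r, seed = 54)
  target <- r^abs(outer(1:12, 1:12, "-"))
  expect_lt(norm(cov(x) - target, "F"), 0.1)
})

test_that("log survival times follow the componentwise power model", {
  x <- matrix(c(1, -1, 2, 0), 2)
  w <- c(1, 0.5)
  expect_equal(survival_times(x, w, k = 1, sigma = 0), drop(x %*% w))
  # k = 2 squares componentwise: signal for column 1 = (1, 1)
  expect_equal(survival_times(x, c(1, 0), k = 2, sigma = 0), c(1, 1))
  s1 <- survival_times(x, w, k = 1, sigma = 1, seed = 55)
  s2 <- survival_times(x, w, k = 1, sigma = 1, seed = 55)
  expect_identical(s1, s2)
})

test_that("uniform multiplicative censoring has fraction 1 - C", {
  tt <- exp(rnorm(2000, 3))
  all_events <- apply_censoring(tt, C = 1.2, seed = 56)
  expect_equal(all_events$status, rep(1, 2000))
  expect_equal(all_events$time, tt)

  for (C in c(0.4, 0.5, 0.6)) {
    cen <- apply_censoring(tt, C = C, seed = 57)
    expect_lt(abs(mean(cen$status == 0) - (1 - C)), 0.03)
    expect_true(all(cen$time <= tt))
    expect_true(all(cen$time[cen$status == 1] == tt[cen$status == 1]))
  }
  expect_error(apply_censoring(c(1, -1), 0.5), class = "kernaft_error_time")
})

test_that("make_dataset is deterministic and returns the configured truth", {
  cfg <- simulation_config(w_pattern = sparse_w(magnitude = 0.2, m = 400),
                           seed = 58)
  s1 <- make_dataset(cfg)
  s2 <- make_dataset(cfg)
  expect_identical(s1$train$x, s2$train$x)
  expect_identical(s1$test$time, s2$test$time)

  truth <- s1$truth
  expect_equal(sum(truth != 0), 12)
  expect_equal(unname(truth[seq(1, 51, 10)]), rep(0.2, 6))
  expect_equal(unname(truth[seq(61, 111, 10)]), rep(-0.2, 6))
})

test_that("noise calibration follows the signal-to-noise rule", {
  expect_equal(simulation_config()$sigma, 1)                    # 3 / 3
  expect_equal(simulation_config(
    w_pattern = sparse_w(magnitude = 0.2, m = 200))$sigma, 0.2)
  expect_equal(simulation_config(sigma = 0.7)$sigma, 0.7)       # override
  # mean log survival time is anchored at mean_log_time
  cfg <- simulation_config(n_train = 4000, n_test = 10, seed = 59)
  sim <- make_dataset(cfg)
  expect_lt(abs(mean(log(sim$train$time[sim$train$status == 1])) - 3), 0.4)
})

test_that("quadratic designs are mean-anchored through the even moment", {
  # with k = 2 and sum(w) != 0 the E[x^2] = 1 shift must be removed
  cfg <- simulation_config(n_train = 3000, n_test = 10, m = 4,
                           w_pattern = c(1, 1, 0, 0), k = 2, C = 2, seed = 60)
  sim <- make_dataset(cfg)
  expect_lt(abs(mean(sim$train$log_time) - 3), 0.4)
})

test_that("adding noise features leaves signal and outcomes unchanged", {
  pos <- seq(1, 111, 10)
  cfg1 <- simulation_config(w_pattern = sparse_w(magnitude = 1, m = 500),
                            seed = 61)
  cfg2 <- simulation_config(w_pattern = sparse_w(magnitude = 1, m = 2000),
                            seed = 61)
  s1 <- make_dataset(cfg1)
  s2 <- make_dataset(cfg2)
  expect_identical(s1$train$x[, pos], s2$train$x[, pos])
  expect_identical(s1$train$time, s2$train$time)
  expect_identical(s1$train$status, s2$train$status)
  expect_identical(s1$test$time, s2$test$time)
})

test_that("the sparse layout keeps the signal block correlated and noise independent", {
  cfg <- simulation_config(w_pattern = sparse_w(magnitude = 1, m = 300),
                           n_train = 3000, seed = 62)
  sim <- make_dataset(cfg)
  x <- sim$train$x
  pos <- seq(1, 111, 10)
  block_adj <- sapply(1:11, function(i) cor(x[, pos[i]], x[, pos[i + 1]]))
  expect_true(all(abs(block_adj - 0.4) < 0.06))
  expect_lt(abs(cor(x[, 2], x[, 3])), 0.06)  # noise columns independent
})
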