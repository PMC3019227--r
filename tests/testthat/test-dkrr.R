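test_that("index function encodes event/censoring activity", {
  expect_equal(index_function(1, 5, 2), 1L)   # events always active
  expect_equal(index_function(0, 1, 2), 1L)   # fit below censoring time
  expect_equal(index_function(0, 3, 2), 0L)   # constraint satisfied
  expect_equal(index_function(c(1, 0, 0), c(0, 0, 9), c(1, 1, 1)),
               c(1L, 1L, 0L))
})

test_that("dual sweeps converge to the linear-solve oracle when uncensored", {
  sim <- uncensored_sim(n = 30, seed = 21)
  d <- sim$train
  k <- center_gram(eval_kernel(kernel_spec("linear"), d$x))$k_train
  yc <- d$log_time - mean(d$log_time)
  lambda <- 0.05
  a <- numeric(30)
  for (i in 1:5000) {
    a <- dual_sweep(a, k, yc, d$status, lambda)
    if (attr(a, "max_change") < 1e-12) break
  }
  expect_equal(as.vector(a), drop(ridge_dual_oracle(k, yc, lambda)),
               tolerance = 1e-8)
})

test_that("a = 0 is a fixed point when all censored constraints hold", {
  # all delta = 0 with negative centred targets: fitted 0 > y everywhere
  k <- diag(4) + 1
  y <- rep(-1, 4)
  a <- dual_sweep(numeric(4), k, y, rep(0, 4), lambda = 0.1)
  expect_equal(as.vector(a), rep(0, 4))
})

test_that("dual_sweep demands a positive penalty", {
  expect_error(dual_sweep(numeric(2), diag(2), c(1, -1), c(1, 1), 0),
               class = "kernaft_error_lambda")
})

test_that("uncensored DKRR matches closed-form kernel ridge", {
  sim <- uncensored_sim(n = 40, seed = 22)
  d <- sim$train
  for (sp in default_kernels()) {
    fit <- fit_dkrr(d, sp, lambda = 0.05, eps = 1e-11)
    sp_used <- fit$spec # rbf sigma resolved
    k <- center_gram(eval_kernel(sp_used, d$x))$k_train
    a_star <- ridge_dual_oracle(k, d$log_time - mean(d$log_time), 0.05)
    expect_lt(max(abs(fit$a - a_star)), 1e-8)
  }
})

test_that("duplicated samples receive identical fits", {
  sim <- uncensored_sim(n = 20, seed = 23)
  d <- sim$train
  dup <- survival_dataset(rbind(d$x, d$x), c(d$time, d$time),
                          c(d$status, d$status))
  fit <- fit_dkrr(dup, kernel_spec("linear"), 0.1)
  expect_equal(fit$fitted[1:20], fit$fitted[21:40], tolerance = 1e-6)
})

test_that("a huge penalty shrinks to the training mean", {
  sim <- censored_sim(seed = 24)
  fit <- fit_dkrr(sim$train, kernel_spec("linear"), lambda = 1e6)
  expect_lt(max(abs(fit$a)), 1e-4)
  pred <- predict(fit, sim$test)
  expect_lt(max(abs(pred - mean(sim$train$log_time))), 0.05)
})

test_that("noiseless linear data are interpolated at small lambda", {
  cfg <- simulation_config(n_train = 40, n_test = 20, m = 6,
                           w_pattern = rep(c(1, -1), 3), sigma = 0,
                           C = 2, seed = 25)
  sim <- make_dataset(cfg)
  fit <- fit_dkrr(sim$train, kernel_spec("linear"), lambda = 1e-6,
                  eps = 1e-10)
  expect_lt(rrmse(sim$train$log_time, fit$fitted), 0.05)
  # a test row equal to a training row predicts that row's fitted value
  pred1 <- predict(fit, sim$train$x[3, , drop = FALSE])
  expect_equal(pred1, fit$fitted[3], tolerance = 1e-8)
})

test_that("at convergence, satisfied censored constraints have zero duals", {
  sim <- censored_sim(n = 80, seed = 26)
  fit <- fit_dkrr(sim$train, kernel_spec("linear"), 0.05)
  cen <- sim$train$status == 0
  inactive <- cen & (fit$fitted > sim$train$log_time + 1e-10)
  expect_true(any(inactive))
  expect_equal(unname(fit$a[inactive]), rep(0, sum(inactive)))
})

test_that("the dual objective decreases monotonically and the primal overall", {
  sim <- uncensored_sim(n = 40, seed = 27)
  d <- sim$train
  k <- center_gram(eval_kernel(kernel_spec("linear"), d$x))$k_train
  yc <- d$log_time - mean(d$log_time)
  n <- 40; lambda <- 0.02
  dual_obj <- function(a) {
    0.5 * drop(t(a) %*% (k + n * lambda * diag(n)) %*% a) - sum(yc * a)
  }
  primal_obj <- function(a) {
    r <- drop(k %*% a) - yc
    sum(r^2) / (2 * n) + lambda / 2 * drop(t(a) %*% k %*% a)
  }
  a <- numeric(n)
  f_path <- dual_obj(a)
  for (i in 1:100) {
    a <- dual_sweep(a, k, yc, d$status, lambda)
    f_path <- c(f_path, dual_obj(a))
  }
  expect_true(all(diff(f_path) <= 1e-10))
  expect_lt(primal_obj(a), primal_obj(numeric(n)))
})

test_that("the converged solution is insensitive to the starting point", {
  sim <- censored_sim(n = 60, seed = 28)
  d <- sim$train
  k <- center_gram(eval_kernel(kernel_spec("linear"), d$x))$k_train
  yc <- d$log_time - mean(d$log_time)
  run_from <- function(a0) {
    a <- a0
    for (i in 1:10000) {
      a <- dual_sweep(a, k, yc, d$status, 0.05)
      if (attr(a, "max_change") < 1e-9) break
    }
    drop(a)
  }
  set.seed(28)
  a_zero <- run_from(numeric(60))
  a_rand <- run_from(runif(60) * 0.1)
  expect_lt(max(abs(a_zero - a_rand)), 0.01)
})

test_that("prediction validates dimensions and anchors at a = 0", {
  sim <- censored_sim(seed = 29)
  fit <- fit_dkrr(sim$train, kernel_spec("linear"), 0.1)
  expect_error(predict(fit, matrix(1, 2, 3)), class = "kernaft_error_dim")
  fit$a[] <- 0
  expect_equal(predict(fit, sim$test),
               rep(mean(sim$train$log_time), 20))
})

test_that("tidy and glance summarise a DKRR fit", {
  sim <- censored_sim(seed = 30)
  fit <- fit_dkrr(sim$train, kernel_spec("polynomial", degree = 2), 0.1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 60)
  gl <- glance(fit)
  expect_equal(gl$kernel, "polynomial")
  expect_true(gl$converged)
})
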