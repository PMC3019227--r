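test_that("the reweighted design and adaptive Gram follow their definitions", {
  set.seed(31)
  x <- matrix(rnorm(24), 4)
  # unit weights leave X untouched, any p
  for (p in c(0.3, 0.6, 1)) {
    expect_equal(build_xu(x, rep(1, 6), p), x)
  }
  # a zero weight drops its column
  u <- rep(1, 6); u[3] <- 0
  expect_equal(build_xu(x, u, 0.6)[, 3], rep(0, 4))
  # hand example: identity design, u = (2, 1), p = 1 -> diag(2, 1)
  expect_equal(build_xu(diag(2), c(2, 1), 1), diag(c(2, 1)))

  expect_equal(adaptive_gram(x, rep(1, 6), 0.6), tcrossprod(x))
  # single nonzero weight: scaled rank-one outer product
  u1 <- rep(0, 6); u1[2] <- 2
  expect_equal(adaptive_gram(x, u1, 0.5),
               2^1.5 * tcrossprod(x[, 2]), tolerance = 1e-12)
  ku <- adaptive_gram(x, rnorm(6), 0.7)
  expect_equal(ku, t(ku), tolerance = 1e-12)
  expect_error(build_xu(x, 1:3, 0.6), class = "kernaft_error_dim")
  expect_error(build_xu(x, rep(1, 6), 1.5), class = "kernaft_error_p")
})

test_that("with frozen u the inner dual solves the weighted ridge system", {
  sim <- uncensored_sim(n = 30, m = 10, seed = 32)
  d <- sim$train
  set.seed(32)
  u <- runif(10, 0.2, 1)
  p <- 0.6; lambda <- 0.05
  xc <- sweep(d$x, 2, colMeans(d$x))
  yc <- d$log_time - mean(d$log_time)
  ku <- adaptive_gram(xc, u, p)
  a <- numeric(30)
  for (i in 1:5000) {
    a <- dual_sweep(a, ku, yc, d$status, lambda)
    if (attr(a, "max_change") < 1e-13) break
  }
  a_star <- solve(ku + 30 * lambda * diag(30), yc)
  expect_lt(max(abs(a - a_star)), 1e-6)
  w <- drop(crossprod(build_xu(xc, u, p), a))
  w_star <- drop(diag(abs(u)^(2 - p)) %*% t(xc) %*% a_star)
  expect_lt(max(abs(w - w_star)), 1e-6)
})

test_that("a single active feature is recovered with the right sign", {
  set.seed(33)
  x <- matrix(rnorm(60 * 5), 60)
  log_t <- 3 + 1.5 * x[, 4]          # noiseless, single feature, positive
  d <- survival_dataset(x, exp(log_t), rep(1, 60))
  fit <- fit_akrr(d, lambda = 0.01, p = 1)
  expect_equal(fit$selected, 4L)
  expect_gt(fit$w[4], 0)
})

test_that("a dominating penalty empties the selection", {
  sim <- censored_sim(n = 40, m = 10, seed = 34)
  fit <- fit_akrr(sim$train, lambda = 1, p = 0.6)
  expect_length(fit$selected, 0)
  expect_equal(unname(fit$w), rep(0, 10))
  # all-zero coefficients predict the anchor
  expect_equal(predict(fit, sim$test),
               rep(mean(sim$train$log_time), 20))
})

test_that("the sparse design is recovered at the study settings", {
  cfg <- simulation_config(w_pattern = sparse_w(magnitude = 1, m = 500),
                           seed = 35)
  sim <- make_dataset(cfg)
  fit <- fit_akrr(sim$train, lambda = 0.01, p = 0.6)
  truth <- which(sim$truth != 0)
  expect_gte(sum(truth %in% fit$selected), 11)
  expect_lte(length(fit$selected), 16)
  expect_true(fit$converged)
  # signs agree with the truth on the recovered support
  hit <- intersect(fit$selected, truth)
  expect_true(all(sign(fit$w[hit]) == sign(sim$truth[hit])))
})

test_that("fits are deterministic and init-robust on well-separated signals", {
  # same-sign, well-spaced signals: restarts agree exactly
  w <- numeric(200); w[seq(1, 111, 10)] <- 1
  cfg <- simulation_config(m = 200, w_pattern = w, seed = 36)
  sim <- make_dataset(cfg)
  f1 <- fit_akrr(sim$train, 0.01, 0.8)
  f2 <- fit_akrr(sim$train, 0.01, 0.8)
  expect_identical(f1$w, f2$w)
  sels <- lapply(1:5, function(s)
    fit_akrr(sim$train, 0.01, 0.8, init = "random", seed = s)$selected)
  # every restart recovers the full truth, with at most an occasional
  # idiosyncratic extra; the consensus across restarts is exactly the truth
  truth <- unname(which(sim$truth != 0))
  for (s in sels) {
    expect_true(all(truth %in% s))
    expect_lte(length(s), 14)
  }
  expect_equal(sort(Reduce(intersect, sels)), truth)
})

test_that("multistart reduces to a single fit and respects the holdout", {
  cfg <- simulation_config(w_pattern = sparse_w(magnitude = 1, m = 200),
                           seed = 37)
  sim <- make_dataset(cfg)
  single <- fit_akrr(sim$train, 0.01, 0.6, init = "random", seed = 5)
  multi1 <- fit_akrr_multistart(sim$train, 0.01, 0.6, n_restarts = 1,
                                seed = 5)
  expect_equal(single$w, multi1$w)
  expect_error(fit_akrr_multistart(sim$train, 0.01, 0.6, n_restarts = 3),
               class = "kernaft_error_input")
  multi <- fit_akrr_multistart(sim$train, 0.01, p = 0.3, n_restarts = 4,
                               holdout = sim$test, seed = 9)
  expect_s3_class(multi, "akrr_fit")
  expect_true(is.finite(multi$holdout_rrmse))
  # low p still keeps a core of the strongest features
  expect_gte(sum(which(sim$truth != 0) %in% multi$selected), 5)
})

test_that("noiseless uncensored fits interpolate the training outcomes", {
  cfg <- simulation_config(n_train = 60, n_test = 20, m = 20,
                           w_pattern = c(rep(c(1, -1), 3), rep(0, 14)),
                           sigma = 0, C = 2, seed = 38)
  sim <- make_dataset(cfg)
  fit <- fit_akrr(sim$train, lambda = 1e-4, p = 1, eps = 1e-7)
  pred <- predict(fit, sim$train)
  expect_lt(rrmse(sim$train$log_time, pred), 0.05)
})

test_that("a constant feature is never selected", {
  sim <- censored_sim(n = 50, m = 8, seed = 39)
  x <- cbind(sim$train$x, const = 7)
  d <- survival_dataset(x, sim$train$time, sim$train$status)
  fit <- fit_akrr(d, 0.01, 0.6)
  expect_false(9L %in% fit$selected)
  expect_equal(unname(fit$w[9]), 0)
})

test_that("per-fit cost scales with the active set, not m^2", {
  # m = 20,000 fit finishes fast because dropped columns leave the Gram
  cfg <- simulation_config(w_pattern = sparse_w(magnitude = 1, m = 20000),
                           seed = 40)
  sim <- make_dataset(cfg)
  el <- system.time(fit <- fit_akrr(sim$train, 0.01, 0.6))[["elapsed"]]
  expect_lt(el, 30)
  expect_true(fit$converged)
})

test_that("tidy and glance summarise an AKRR fit", {
  cfg <- simulation_config(w_pattern = sparse_w(magnitude = 1, m = 300),
                           seed = 41)
  sim <- make_dataset(cfg)
  fit <- fit_akrr(sim$train, 0.01, 0.6)
  td <- tidy(fit)
  expect_true(all(td$index[td$selected] %in% fit$selected))
  expect_equal(nrow(tidy(fit, all = TRUE)), 300)
  expect_equal(glance(fit)$n_selected, length(fit$selected))
})
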