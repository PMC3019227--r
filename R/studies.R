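# Prepackaged simulation studies: the kernel-comparison RRMSE protocol and
# the dimension-robustness study. These drive the reproduce subcommand and
# the acceptance script.

#' Kernel comparison study on simulated AFT data
#'
#' For each correlation `r` and replicate, draws the dense 12-feature design
#' (`n_train = n_test = 100`, coefficients +-1, SNR 3:1, ~50% censoring) with
#' signal power `k`, fits DKRR with each kernel (ridge penalty chosen by
#' k-fold cross-validation on the training split), and records the test
#' [rrmse()] over events.
#'
#' @param k Componentwise signal power (1 = linear truth, 2 = quadratic).
#' @param kernels Named list of [kernel_spec()]s to compare.
#' @param rs AR correlations to average over.
#' @param n_replicates Replicates per correlation.
#' @param lambdas Cross-validation grid for the ridge penalty.
#' @param folds CV folds.
#' @param seed Base seed.
#' @return Tibble: `k`, `kernel`, `r`, `replicate`, `lambda`, `rrmse`.
#' @export
kernel_rrmse_study <- function(k = c(1, 2),
                               kernels = default_kernels(),
                               rs = c(0.2, 0.4, 0.6, 0.8),
                               n_replicates = 20,
                               lambdas = 10^seq(-3, 0, length.out = 7),
                               folds = 5, seed = 1) {
  rows <- list()
  for (kk in k) {
    for (r in rs) {
      for (i in seq_len(n_replicates)) {
        cfg <- simulation_config(
          r = r, k = kk,
          seed = (seed + 7919L * kk + 104729L * match(r, rs) + i) %%
            (.Machine$integer.max - 1L))
        sim <- make_dataset(cfg)
        for (kn in names(kernels)) {
          cv <- cv_dkrr(sim$train, kernels[[kn]], lambdas, folds,
                        seed = cfg$seed)
          fit <- fit_dkrr(sim$train, kernels[[kn]], cv$best_lambda)
          pred <- predict(fit, sim$test)
          keep <- sim$test$status == 1
          rows[[length(rows) + 1]] <- tibble::tibble(
            k = kk, kernel = kn, r = r, replicate = i,
            lambda = cv$best_lambda,
            rrmse = suppressWarnings(
              rrmse(sim$test$log_time[keep], pred[keep]))
          )
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Default kernel set for the comparison study
#'
#' Linear, second- and third-order polynomial (offset 1), and rbf with the
#' median-distance bandwidth.
#'
#' @return Named list of [kernel_spec()]s.
#' @export
default_kernels <- function() {
  list(
    linear = kernel_spec("linear"),
    poly2 = kernel_spec("polynomial", degree = 2),
    poly3 = kernel_spec("polynomial", degree = 3),
    rbf = kernel_spec("rbf")
  )
}

#' Dimension-robustness study for AKRR
#'
#' Repeats the sparse selection design at several feature counts `m`, reusing
#' the same signal, outcome and censoring draws at every `m` (only the number
#' of independent noise features changes), and records test RRMSE and
#' selection scores. Used to check that performance does not degrade as the
#' dimension grows from hundreds to tens of thousands.
#'
#' @param dims Feature counts to compare (each >= 112 so the default sparse
#'   layout fits).
#' @param magnitude True coefficient magnitude.
#' @param lambda,p Penalty settings for [fit_akrr()].
#' @param n_replicates Replicates per dimension.
#' @param seed Base seed.
#' @return Tibble: `m`, `replicate`, `rrmse`, `n_selected`, `n_true_hit`.
#' @export
dimension_study <- function(dims = c(100, 1000, 10000), magnitude = 1,
                            lambda = 0.01, p = 0.6, n_replicates = 20,
                            seed = 1) {
  dims <- pmax(dims, 112L)
  rows <- list()
  for (i in seq_len(n_replicates)) {
    for (m in dims) {
      cfg <- simulation_config(
        w_pattern = sparse_w(magnitude = magnitude, m = m),
        seed = (seed + i) %% (.Machine$integer.max - 1L))
      sim <- make_dataset(cfg)
      fit <- fit_akrr(sim$train, lambda, p)
      pred <- predict(fit, sim$test)
      keep <- sim$test$status == 1
      sc <- score_selection(fit$selected, which(sim$truth != 0))
      rows[[length(rows) + 1]] <- tibble::tibble(
        m = m, replicate = i,
        rrmse = suppressWarnings(
          rrmse(sim$test$log_time[keep], pred[keep])),
        n_selected = sc$n_selected, n_true_hit = sc$n_true_hit
      )
    }
  }
  dplyr::bind_rows(rows)
}
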