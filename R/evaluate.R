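#' Relative root mean squared error
#'
#' `rrmse = sqrt( mean( ((y - yhat) / y)^2 ) )`, the package's predictive
#' metric on log survival times. Terms with `|y| < min_abs_y` are excluded
#' (with a warning) because the per-sample relative error is undefined at
#' `y = 0`.
#'
#' @param y Observed values (typically log survival times of test events).
#' @param yhat Predictions.
#' @param min_abs_y Exclusion threshold for near-zero denominators.
#' @return A non-negative scalar.
#' @examples
#' rrmse(c(2, 2), c(1, 3))  # 0.5
#' @export
rrmse <- function(y, yhat, min_abs_y = 1e-8) {
  if (length(y) != length(yhat)) {
    abort("`y` and `yhat` must have equal length.",
          class = "kernaft_error_dim")
  }
  keep <- abs(y) >= min_abs_y
  if (!all(keep)) {
    warn(sprintf("rrmse: dropped %d term(s) with |y| < %g.",
                 sum(!keep), min_abs_y))
  }
  if (!any(keep)) {
    abort("rrmse: no usable terms (all |y| below threshold).",
          class = "kernaft_error_input")
  }
  sqrt(mean(((y[keep] - yhat[keep]) / y[keep])^2))
}

#' Score a selected variable set against the known truth
#'
#' Three-way classification used for simulation summaries: `exact_match` when
#' the selected set equals the truth support; `overfit` when every true
#' variable is selected plus at least one extra; `underfit` when at least one
#' true variable is missed (this takes precedence when extras are also
#' present).
#'
#' @param selected Integer indices of selected variables.
#' @param truth_support Integer indices of truly nonzero variables.
#' @return A one-row tibble: `n_selected`, `n_true_hit`, `exact_match`,
#'   `overfit`, `underfit`.
#' @export
score_selection <- function(selected, truth_support) {
  selected <- unique(as.integer(selected))
  truth_support <- unique(as.integer(truth_support))
  hit <- sum(truth_support %in% selected)
  all_true <- hit == length(truth_support)
  tibble::tibble(
    n_selected = length(selected),
    n_true_hit = hit,
    exact_match = all_true && length(selected) == length(truth_support),
    overfit = all_true && length(selected) > length(truth_support),
    underfit = !all_true
  )
}

make_folds <- function(n, folds, seed = NULL) {
  if (folds > n) {
    abort("`folds` exceeds the number of samples.",
          class = "kernaft_error_input")
  }
  if (!is.null(seed)) set.seed(seed)
  sample(rep(seq_len(folds), length.out = n))
}

cv_rrmse_split <- function(truth, pred, status) {
  keep <- status == 1
  if (!any(keep)) return(NA_real_)
  suppressWarnings(rrmse(truth[keep], pred[keep]))
}

#' Cross-validated ridge penalty selection for DKRR
#'
#' k-fold cross-validation of the test [rrmse()] (events only) over a grid of
#' `lambda` values, using the training data alone.
#'
#' @param data A [survival_dataset()].
#' @param spec A [kernel_spec()].
#' @param lambdas Candidate penalties in (0, 1].
#' @param folds Number of folds.
#' @param seed Seed for the fold assignment.
#' @param eps,max_iter Passed to [fit_dkrr()].
#' @return A list with `best_lambda` and a `grid` tibble
#'   (`lambda`, `mean_rrmse`, `sd_rrmse`).
#' @export
cv_dkrr <- function(data, spec = kernel_spec("linear"),
                    lambdas = 10^seq(-3, 0, length.out = 7), folds = 5,
                    seed = NULL, eps = 1e-6, max_iter = 10000L) {
  data <- as_survival_dataset(data)
  fold_id <- make_folds(nrow(data$x), folds, seed)
  err <- matrix(NA_real_, folds, length(lambdas))
  for (f in seq_len(folds)) {
    tr <- data[fold_id != f]
    te <- data[fold_id == f]
    for (li in seq_along(lambdas)) {
      fit <- fit_dkrr(tr, spec, lambdas[li], eps, max_iter)
      err[f, li] <- cv_rrmse_split(te$log_time, predict(fit, te), te$status)
    }
  }
  grid <- tibble::tibble(
    lambda = lambdas,
    mean_rrmse = colMeans(err, na.rm = TRUE),
    sd_rrmse = apply(err, 2, stats::sd, na.rm = TRUE)
  )
  list(best_lambda = lambdas[which.min(grid$mean_rrmse)], grid = grid)
}

#' Cross-validated (lambda, p) grid search for AKRR with relevance counts
#'
#' Repeated k-fold cross-validation of the sparse AFT fit over a grid of
#' penalty weights and exponents, using the supplied (training) data only.
#' For every grid point the mean and sd of the held-out [rrmse()] (events
#' only) are recorded; the best point minimises the mean. For each fold fit at
#' the best grid point, the selected features are tallied into per-feature
#' relevance counts: with `folds = 2` and `repeats = 100` the maximum count is
#' 200, the stability score used to rank genes.
#'
#' @param data A [survival_dataset()] (training split only).
#' @param lambdas Candidate penalty weights in (0, 1].
#' @param ps Candidate exponents in (0, 1].
#' @param folds Folds per repeat.
#' @param repeats Number of random fold assignments.
#' @param seed Seed for fold assignments.
#' @param eta,eps,max_outer,inner_sweeps Passed to [fit_akrr()].
#' @return A `cv_result` list: `grid` tibble (`lambda`, `p`, `mean_rrmse`,
#'   `sd_rrmse`), `best_lambda`, `best_p`, and `relevance_counts` (tibble
#'   `feature`, `index`, `count` at the best grid point).
#' @export
grid_search <- function(data, lambdas, ps = c(0.6, 0.7, 0.8, 0.9, 1),
                        folds = 10, repeats = 1, seed = 1, eta = 1/3,
                        eps = 1e-4, max_outer = 500L, inner_sweeps = 5L) {
  data <- as_survival_dataset(data)
  if (any(lambdas <= 0) || any(lambdas > 1)) {
    abort("`lambdas` must lie in (0, 1].", class = "kernaft_error_lambda")
  }
  n <- nrow(data$x)
  m <- ncol(data$x)
  grid <- tidyr::expand_grid(p = sort(ps, decreasing = TRUE),
                             lambda = sort(lambdas, decreasing = TRUE))
  errs <- matrix(NA_real_, nrow(grid), folds * repeats)
  counts <- array(0L, dim = c(nrow(grid), m))
  for (rep_i in seq_len(repeats)) {
    fold_id <- make_folds(n, folds, seed + rep_i - 1)
    for (f in seq_len(folds)) {
      tr <- data[fold_id != f]
      te <- data[fold_id == f]
      for (g in seq_len(nrow(grid))) {
        fit <- fit_akrr(tr, grid$lambda[g], grid$p[g], eta, eps,
                        max_outer, inner_sweeps)
        errs[g, (rep_i - 1) * folds + f] <-
          cv_rrmse_split(te$log_time, predict(fit, te), te$status)
        counts[g, fit$selected] <- counts[g, fit$selected] + 1L
      }
    }
  }
  grid$mean_rrmse <- rowMeans(errs, na.rm = TRUE)
  grid$sd_rrmse <- apply(errs, 1, stats::sd, na.rm = TRUE)
  best <- which.min(grid$mean_rrmse)
  out <- list(
    grid = tibble::as_tibble(grid),
    best_lambda = grid$lambda[best],
    best_p = grid$p[best],
    relevance_counts = tibble::tibble(
      feature = colnames(data$x) %||% paste0("x", seq_len(m)),
      index = seq_len(m),
      count = counts[best, ]
    ),
    folds = folds, repeats = repeats
  )
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> best lambda = %g, p = %g (mean RRMSE %.4g); %d x %d-fold CV\n",
    x$best_lambda, x$best_p,
    min(x$grid$mean_rrmse, na.rm = TRUE), x$repeats, x$folds))
  invisible(x)
}

#' Replicated selection study on simulated data
#'
#' Runs `make_dataset -> fit_akrr -> score_selection` over independent
#' replicates of one simulation design and aggregates per-variable selection
#' frequencies (the Table-style counts for the true variables), the mean
#' selected-set size, the exact-match / overfitting / underfitting
#' percentages, and the test RRMSE.
#'
#' @param config A [simulation_config()]; replicate `i` uses `seed + i - 1`.
#' @param lambda,p,eta,eps,max_outer,inner_sweeps Passed to [fit_akrr()].
#' @param n_replicates Number of independent replicates.
#' @return An `akrr_replicates` object: `replicates` (per-replicate tibble),
#'   `frequency` (per-true-variable selection counts), `summary` (one-row
#'   tibble), and `config`.
#' @export
replicate_study <- function(config, lambda, p = 0.6, n_replicates = 100,
                            eta = 1/3, eps = 1e-4, max_outer = 500L,
                            inner_sweeps = 5L) {
  stopifnot(inherits(config, "simulation_config"))
  truth_support <- which(config$w != 0)
  sel_count <- integer(length(config$w))
  reps <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg_i <- config
    cfg_i$seed <- (config$seed + i - 1L) %% (.Machine$integer.max - 1L)
    sim <- make_dataset(cfg_i)
    fit <- fit_akrr(sim$train, lambda, p, eta, eps, max_outer, inner_sweeps)
    sel_count[fit$selected] <- sel_count[fit$selected] + 1L
    pred <- predict(fit, sim$test)
    sc <- score_selection(fit$selected, truth_support)
    sc$replicate <- i
    sc$rrmse <- cv_rrmse_split(sim$test$log_time, pred, sim$test$status)
    sc$converged <- fit$converged
    reps[[i]] <- sc
  }
  replicates <- dplyr::bind_rows(reps)
  summary <- tibble::tibble(
    n_replicates = n_replicates, lambda = lambda, p = p, eta = eta,
    mean_n_selected = mean(replicates$n_selected),
    pct_exact = 100 * mean(replicates$exact_match),
    pct_overfit = 100 * mean(replicates$overfit),
    pct_underfit = 100 * mean(replicates$underfit),
    pct_all_true = 100 * mean(replicates$n_true_hit == length(truth_support)),
    pct_ge10_true = 100 * mean(replicates$n_true_hit >=
                                 min(10, length(truth_support))),
    pct_size_11_13 = 100 * mean(replicates$n_selected >= 11 &
                                  replicates$n_selected <= 13),
    mean_rrmse = mean(replicates$rrmse, na.rm = TRUE),
    median_rrmse = stats::median(replicates$rrmse, na.rm = TRUE)
  )
  structure(
    list(
      replicates = replicates,
      frequency = tibble::tibble(
        index = truth_support,
        coefficient = config$w[truth_support],
        count = sel_count[truth_support],
        frequency = sel_count[truth_support] / n_replicates
      ),
      summary = summary,
      config = config
    ),
    class = "akrr_replicates"
  )
}

#' @export
print.akrr_replicates <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<akrr_replicates> %d replicates (lambda = %g, p = %g): mean #selected %.2f; exact %.0f%%, overfit %.0f%%, underfit %.0f%%\n",
    s$n_replicates, s$lambda, s$p, s$mean_n_selected, s$pct_exact,
    s$pct_overfit, s$pct_underfit))
  invisible(x)
}

#' @describeIn replicate_study Per-replicate tidy table.
#' @param x An `akrr_replicates`.
#' @param ... Unused.
#' @method tidy akrr_replicates
#' @export
tidy.akrr_replicates <- function(x, ...) x$replicates

#' @describeIn replicate_study One-row summary.
#' @method glance akrr_replicates
#' @export
glance.akrr_replicates <- function(x, ...) x$summary
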