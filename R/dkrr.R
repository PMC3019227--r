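#' Censoring index function
#'
#' Per-sample activity flag of the censored kernel ridge loss: samples with an
#' observed event always contribute; a right-censored sample contributes only
#' while its current fitted log-time does not exceed its log censoring time
#' (i.e. while the lower-bound constraint is violated).
#'
#' @param delta Event indicator(s), 0/1.
#' @param fitted Current fitted log-time(s).
#' @param log_time Observed log-time(s) (log censoring time where `delta = 0`).
#' @return Integer 0/1 vector.
#' @examples
#' index_function(1, 5, 2)  # events are always active
#' index_function(0, 1, 2)  # fitted below censoring time: constraint violated
#' index_function(0, 3, 2)  # constraint satisfied: inactive
#' @export
index_function <- function(delta, fitted, log_time) {
  as.integer(delta == 1 | fitted <= log_time)
}

#' Gauss-Seidel sweeps on the dual coordinates
#'
#' Performs full passes `i = 1, ..., n` of coordinate updates on the dual
#' variables of the censored kernel ridge system. Each coordinate is set to
#' the exact minimiser of the objective in `a_i` given the others,
#' `a_i = (y_i - K_i.a + K_ii a_i) / (K_ii + n lambda)`, whose stationary
#' point satisfies `a_i = -I(delta_i) (K_i.a - y_i) / (n lambda)`; censored
#' samples whose fit already exceeds their log censoring time are clamped to
#' `a_i = 0`. Updates use the freshest values of already-updated coordinates,
#' and the censoring index is re-evaluated at the moment each coordinate is
#' visited.
#'
#' @param a Current dual vector (length n).
#' @param k Centred symmetric `n x n` Gram matrix.
#' @param log_time_centered Centred log-times.
#' @param delta Event indicators.
#' @param lambda Ridge penalty, must be positive.
#' @param sweeps Number of full passes.
#' @return The updated dual vector, with attribute `max_change` (infinity norm
#'   of the last pass's update).
#' @export
dual_sweep <- function(a, k, log_time_centered, delta, lambda, sweeps = 1L) {
  check_lambda(lambda)
  res <- gs_sweep_cpp(as.matrix(k), as.numeric(log_time_centered),
                      as.integer(delta), lambda, as.numeric(a),
                      as.integer(sweeps))
  out <- drop(res$a)
  attr(out, "max_change") <- res$max_change
  out
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    abort("`lambda` must be a single positive number.",
          class = "kernaft_error_lambda")
  }
}

#' Fit a censored dual kernel ridge regression (DKRR) AFT model
#'
#' Fits the accelerated failure time model `E[log T | x] = M(x)` by kernel
#' ridge regression solved in the dual: starting from `a = 0`, Gauss-Seidel
#' coordinate sweeps are run on the centred Gram system until the infinity
#' norm of the update falls below `eps`. Events enter as least-squares terms;
#' right-censored samples enter only while the fit violates their lower-bound
#' constraint, so at convergence every censored sample fitted above its
#' censoring time has a zero dual coefficient. With no censoring the solution
#' equals the closed-form kernel ridge estimate `(K + n lambda I)^{-1} y`.
#'
#' @param data A [survival_dataset()] or a data frame with `time` and `status`
#'   columns (see [as_survival_dataset()]).
#' @param spec A [kernel_spec()].
#' @param lambda Positive ridge penalty (the objective is
#'   `sum(I_i (M(x_i) - log T_i)^2) / (2n) + lambda w^t w / 2`).
#' @param eps Convergence tolerance on the infinity norm of a sweep's update.
#' @param max_iter Maximum number of sweeps; non-convergence is reported via
#'   the `converged` flag, not an error.
#' @return A `dkrr_fit` object with dual coefficients `a`, the training
#'   references and centring statistics needed by [predict.dkrr_fit()],
#'   in-sample `fitted` log-times, `n_iter` and `converged`.
#' @examples
#' sim <- make_dataset(simulation_config(n_train = 40, n_test = 10, m = 5,
#'                                       w_pattern = c(1, -1, 0, 0, 0)))
#' fit <- fit_dkrr(sim$train, kernel_spec("linear"), lambda = 0.1)
#' head(predict(fit, sim$test))
#' @export
fit_dkrr <- function(data, spec = kernel_spec("linear"), lambda = 0.01,
                     eps = 1e-6, max_iter = 10000L) {
  data <- as_survival_dataset(data)
  check_lambda(lambda)
  n <- nrow(data$x)
  if (n < 2) abort("Need at least 2 samples.", class = "kernaft_error_input")
  if (spec$family == "rbf" && is.null(spec$sigma)) {
    spec$sigma <- median_heuristic(data$x)
  }
  k <- eval_kernel(spec, data$x)
  gp <- center_gram(k)
  y_mean <- mean(data$log_time)
  yc <- data$log_time - y_mean
  sol <- dkrr_solve_cpp(gp$k_train, yc, as.integer(data$status), lambda,
                        eps, as.integer(max_iter), numeric(n))
  a <- drop(sol$a)
  fitted <- drop(gp$k_train %*% a) + y_mean
  structure(
    list(a = a, lambda = lambda, spec = spec,
         x_train = data$x, train_col_means = gp$train_col_means,
         train_log_time_mean = y_mean, status = data$status,
         log_time = data$log_time, fitted = fitted,
         n_iter = sol$n_iter, converged = sol$converged),
    class = "dkrr_fit"
  )
}

#' Predict log survival times from a DKRR fit
#'
#' Evaluates `M(x) = sum_i a_i K(x_i, x)` on the centred test kernel and adds
#' back the training mean log-time, so predictions are anchored to the
#' training outcome scale and never use test outcomes.
#'
#' @param object A `dkrr_fit`.
#' @param newdata Matrix, data frame or [survival_dataset()] of new rows with
#'   the training feature count.
#' @param ... Unused.
#' @return Numeric vector of predicted log survival times.
#' @export
predict.dkrr_fit <- function(object, newdata, ...) {
  x_new <- extract_x(newdata, ncol(object$x_train))
  kte <- eval_kernel(object$spec, object$x_train, x_new)
  kte_c <- center_test_kernel(kte, object$train_col_means)
  drop(kte_c %*% object$a) + object$train_log_time_mean
}

extract_x <- function(newdata, m_expected) {
  x <- if (inherits(newdata, "survival_dataset")) newdata$x
       else if (is.data.frame(newdata)) {
         as_survival_dataset_or_matrix(newdata)
       } else as.matrix(newdata)
  if (ncol(x) != m_expected) {
    abort(sprintf("`newdata` has %d features; the model was trained on %d.",
                  ncol(x), m_expected), class = "kernaft_error_dim")
  }
  x
}

as_survival_dataset_or_matrix <- function(df) {
  if (all(c("time", "status") %in% names(df))) {
    as_survival_dataset(df)$x
  } else {
    as.matrix(df[setdiff(names(df), "sample_id")])
  }
}

#' @export
print.dkrr_fit <- function(x, ...) {
  cat(sprintf(
    "<dkrr_fit> %s kernel, lambda = %g; n = %d (%d censored); %s in %d sweeps\n",
    x$spec$family, x$lambda, length(x$a), sum(x$status == 0),
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @describeIn fit_dkrr Per-sample tidy summary: dual coefficient, observed
#'   and fitted log-times.
#' @param x A `dkrr_fit`.
#' @param ... Unused.
#' @method tidy dkrr_fit
#' @export
tidy.dkrr_fit <- function(x, ...) {
  tibble::tibble(
    sample = seq_along(x$a), status = x$status, a = x$a,
    log_time = x$log_time, fitted = x$fitted
  )
}

#' @describeIn fit_dkrr One-row model summary.
#' @method glance dkrr_fit
#' @export
glance.dkrr_fit <- function(x, ...) {
  tibble::tibble(
    kernel = x$spec$family, lambda = x$lambda, n = length(x$a),
    n_censored = sum(x$status == 0), n_iter = x$n_iter,
    converged = x$converged,
    train_rrmse = rrmse(x$log_time[x$status == 1], x$fitted[x$status == 1])
  )
}
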