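#' Kernel specification
#'
#' Defines the kernel family and its hyperparameters for the dual AFT
#' solvers. Families:
#' \describe{
#'   \item{linear}{\eqn{K(x, y) = x^t y}}
#'   \item{rbf}{\eqn{K(x, y) = \exp(-|x - y|^2 / \sigma^2)}; `sigma = NULL`
#'     (default) uses the median of pairwise training distances, a standard
#'     scale-robust heuristic.}
#'   \item{polynomial}{\eqn{K(x, y) = (x^t y + c)^d} with degree `degree` and
#'     inhomogeneous offset `offset` (default 1).}
#'   \item{sigmoid}{\eqn{K(x, y) = \tanh(\beta x^t y)}}
#' }
#' Hyperparameters not used by the chosen family are ignored.
#'
#' @param family Kernel family.
#' @param sigma Positive rbf width \eqn{\sigma} (note: the squared distance is
#'   divided by \eqn{\sigma^2}, with no factor 2).
#' @param degree Positive integer polynomial degree.
#' @param offset Polynomial offset.
#' @param beta Sigmoid slope.
#' @return A `kernel_spec` object.
#' @examples
#' kernel_spec("polynomial", degree = 2)
#' @export
kernel_spec <- function(family = c("linear", "rbf", "polynomial", "sigmoid"),
                        sigma = NULL, degree = 2L, offset = 1, beta = 1) {
  family <- match.arg(family)
  if (family == "rbf" && !is.null(sigma) &&
      (!is.numeric(sigma) || sigma <= 0)) {
    abort("`sigma` must be a positive number.", class = "kernaft_error_input")
  }
  if (family == "polynomial" &&
      (!is.numeric(degree) || degree < 1 || degree != round(degree))) {
    abort("`degree` must be a positive integer.",
          class = "kernaft_error_input")
  }
  structure(
    list(family = family, sigma = sigma, degree = as.integer(degree),
         offset = offset, beta = beta),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  par <- switch(x$family,
    linear = "",
    rbf = sprintf(" (sigma = %s)",
                  if (is.null(x$sigma)) "median heuristic" else
                    format(x$sigma)),
    polynomial = sprintf(" (degree = %d, offset = %g)", x$degree, x$offset),
    sigmoid = sprintf(" (beta = %g)", x$beta))
  cat(sprintf("<kernel_spec> %s%s\n", x$family, par))
  invisible(x)
}

#' Median-distance bandwidth heuristic
#'
#' Returns the median Euclidean distance between distinct rows of `x`, the
#' default rbf width.
#'
#' @param x Numeric matrix of training rows.
#' @return A positive scalar.
#' @export
median_heuristic <- function(x) {
  d <- stats::dist(x)
  med <- median(d[d > 0])
  if (!is.finite(med) || med <= 0) 1 else med
}

# squared Euclidean distances between rows of a and rows of b
row_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Evaluate a kernel between two sets of rows
#'
#' Returns the `q x n` matrix with entry `(k, i)` equal to
#' `K(y_k, x_i)` for the given [kernel_spec()]. All four families are
#' symmetric in their arguments, so `eval_kernel(spec, X, X)` is a symmetric
#' Gram matrix.
#'
#' @param spec A [kernel_spec()]. An rbf spec with `sigma = NULL` uses the
#'   median pairwise distance of `x`.
#' @param x Numeric `n x m` matrix (training rows).
#' @param y Numeric `q x m` matrix (defaults to `x`).
#' @return A `q x n` numeric matrix.
#' @examples
#' eval_kernel(kernel_spec("linear"), matrix(c(1, 2), 1), matrix(c(3, 4), 1))
#' @export
eval_kernel <- function(spec, x, y = x) {
  stopifnot(inherits(spec, "kernel_spec"))
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != ncol(y)) {
    abort("`x` and `y` must have the same number of columns.",
          class = "kernaft_error_dim")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("Kernel inputs must be finite.", class = "kernaft_error_input")
  }
  switch(spec$family,
    linear = tcrossprod(y, x),
    polynomial = (tcrossprod(y, x) + spec$offset)^spec$degree,
    sigmoid = tanh(spec$beta * tcrossprod(y, x)),
    rbf = {
      sigma <- spec$sigma %||% median_heuristic(x)
      exp(-row_dist2(y, x) / sigma^2)
    })
}

#' Double-centre train and test Gram matrices
#'
#' Centres the training Gram matrix as \eqn{K_c = (I - 11^t/n) K (I - 11^t/n)}
#' and, when supplied, the test-by-train matrix as
#' \eqn{K_{te,c} = (K_{te} - 1_{n_k} 1_n^t K / n)(I - 11^t/n)}, so that test
#' rows are centred with the training-kernel column means. Centring is applied
#' through row/column mean subtractions (algebraically identical to forming
#' the centring matrices, without the memory cost). After centring, every row
#' and column of the training Gram matrix sums to zero.
#'
#' @param k_train `n x n` Gram matrix.
#' @param k_test Optional `n_k x n` test-by-train kernel matrix.
#' @return A `gram_pair` list: `k_train`, `k_test` (or `NULL`), `centered`,
#'   and `train_col_means` / `train_mean` (the statistics needed to centre
#'   further test kernels).
#' @export
center_gram <- function(k_train, k_test = NULL) {
  k_train <- as.matrix(k_train)
  n <- nrow(k_train)
  if (ncol(k_train) != n) {
    abort("`k_train` must be square.", class = "kernaft_error_dim")
  }
  cm <- colMeans(k_train)
  rm_ <- rowMeans(k_train)
  mu <- mean(k_train)
  kc <- k_train - outer(rm_, rep(1, n)) - outer(rep(1, n), cm) + mu
  out <- list(k_train = kc, k_test = NULL, centered = TRUE,
              train_col_means = cm, train_mean = mu)
  if (!is.null(k_test)) {
    k_test <- as.matrix(k_test)
    if (ncol(k_test) != n) {
      abort("`k_test` must have the same number of columns as `k_train`.",
            class = "kernaft_error_dim")
    }
    out$k_test <- center_test_kernel(k_test, cm)
  }
  class(out) <- "gram_pair"
  out
}

# centre a test-by-train kernel with the training column means:
# (Kte - 1 cm^t)(I - 11^t/n) = Kte - 1 cm^t - rowMeans(Kte - 1 cm^t) 1^t
center_test_kernel <- function(k_test, train_col_means) {
  a <- sweep(k_test, 2, train_col_means)
  a - rowMeans(a)
}
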