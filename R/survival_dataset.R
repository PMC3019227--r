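#' Construct a right-censored survival dataset
#'
#' Bundles a numeric covariate matrix (samples in rows, features in columns)
#' with per-sample follow-up times and event indicators. Times must be
#' strictly positive; they are log-transformed (natural log) on construction,
#' since the accelerated failure time model is linear on the log-time scale.
#'
#' @param x Numeric matrix or data frame of covariates, one row per sample.
#' @param time Positive follow-up times: the event time where `status == 1`,
#'   the censoring time where `status == 0`.
#' @param status Event indicator, 1 = event observed, 0 = right-censored.
#' @param sample_id Optional sample identifiers (default: row names of `x`,
#'   else `sample_1`, `sample_2`, ...).
#'
#' @return An object of class `survival_dataset`: a list with elements `x`
#'   (numeric matrix), `time`, `status`, `log_time` and `sample_id`.
#' @examples
#' d <- survival_dataset(matrix(rnorm(20), 5), time = c(2, 5, 1, 3, 4),
#'                       status = c(1, 0, 1, 1, 0))
#' d
#' @export
survival_dataset <- function(x, time, status, sample_id = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix or data frame.",
          class = "kernaft_error_input")
  }
  n <- nrow(x)
  time <- as.numeric(time)
  status <- as.numeric(status)
  if (length(time) != n || length(status) != n) {
    abort(sprintf("`time` and `status` must have length nrow(x) = %d.", n),
          class = "kernaft_error_input")
  }
  if (anyNA(x) || !all(is.finite(x))) {
    abort("Covariates contain missing or non-finite values.",
          class = "kernaft_error_input")
  }
  if (anyNA(time) || any(time <= 0)) {
    abort("All follow-up times must be strictly positive.",
          class = "kernaft_error_time")
  }
  if (!all(status %in% c(0, 1))) {
    abort("`status` must be binary: 1 = event, 0 = censored.",
          class = "kernaft_error_status")
  }
  if (is.null(sample_id)) {
    sample_id <- rownames(x) %||% paste0("sample_", seq_len(n))
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  structure(
    list(x = x, time = time, status = status, log_time = log(time),
         sample_id = as.character(sample_id)),
    class = "survival_dataset"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce a data frame to a survival dataset
#'
#' All columns other than `time`, `status` and `sample_id` are taken as
#' covariates.
#'
#' @param df A data frame with numeric feature columns plus follow-up time and
#'   event status columns.
#' @param time,status,sample_id Column names.
#' @return A [survival_dataset()].
#' @export
as_survival_dataset <- function(df, time = "time", status = "status",
                                sample_id = "sample_id") {
  if (inherits(df, "survival_dataset")) return(df)
  if (!is.data.frame(df)) {
    abort("`df` must be a data frame.", class = "kernaft_error_input")
  }
  for (col in c(time, status)) {
    if (!col %in% names(df)) {
      abort(sprintf("Column `%s` not found.", col),
            class = "kernaft_error_input")
    }
  }
  ids <- if (sample_id %in% names(df)) as.character(df[[sample_id]]) else NULL
  feat <- setdiff(names(df), c(time, status, sample_id))
  survival_dataset(as.matrix(df[feat]), df[[time]], df[[status]],
                   sample_id = ids)
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf(
    "<survival_dataset> %d samples x %d features; %d events, %d censored (%.0f%%)\n",
    nrow(x$x), ncol(x$x), sum(x$status == 1), sum(x$status == 0),
    100 * mean(x$status == 0)))
  invisible(x)
}

#' @export
dim.survival_dataset <- function(x) dim(x$x)

#' @method as_tibble survival_dataset
#' @export
as_tibble.survival_dataset <- function(x, ...) {
  tibble::as_tibble(cbind(
    tibble::tibble(sample_id = x$sample_id, time = x$time, status = x$status),
    tibble::as_tibble(x$x)
  ))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Subset samples of a survival dataset
#'
#' @param x A [survival_dataset()].
#' @param i Row (sample) index.
#' @param ... Unused.
#' @return A [survival_dataset()] with the selected samples.
#' @export
`[.survival_dataset` <- function(x, i, ...) {
  survival_dataset(x$x[i, , drop = FALSE], x$time[i], x$status[i],
                   sample_id = x$sample_id[i])
}
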