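#' Read a survival dataset from delimited files
#'
#' The covariate file holds one sample per row: a `sample_id` column followed
#' by numeric feature columns (use `transpose = TRUE` for genes-in-rows
#' files). The survival file holds `sample_id`, `time` and `status` columns.
#' The two tables are joined on `sample_id`; missing overlap, non-positive
#' times and non-binary status each raise a distinct, classed error.
#'
#' @param matrix_path Path to the delimited covariate matrix.
#' @param survival_path Path to the delimited survival table.
#' @param delim Field delimiter (default tab). Gzipped files are read
#'   transparently.
#' @param transpose Set when the matrix file stores features in rows and
#'   samples in columns (first column = feature IDs).
#' @return A [survival_dataset()].
#' @export
read_dataset <- function(matrix_path, survival_path, delim = "\t",
                         transpose = FALSE) {
  mat <- readr::read_delim(matrix_path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (transpose) {
    ids <- names(mat)[-1]
    feats <- as.character(mat[[1]])
    x <- t(as.matrix(mat[, -1]))
    colnames(x) <- feats
    mat <- tibble::as_tibble(x)
    mat <- dplyr::bind_cols(tibble::tibble(sample_id = ids), mat)
  }
  if (!"sample_id" %in% names(mat)) {
    names(mat)[1] <- "sample_id"
  }
  surv <- readr::read_delim(survival_path, delim = delim,
                            show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "time", "status")
  if (!all(need %in% names(surv))) {
    abort("Survival file must have columns sample_id, time, status.",
          class = "kernaft_error_input")
  }
  mat$sample_id <- as.character(mat$sample_id)
  surv$sample_id <- as.character(surv$sample_id)
  if (!setequal(mat$sample_id, surv$sample_id)) {
    missing <- c(setdiff(mat$sample_id, surv$sample_id),
                 setdiff(surv$sample_id, mat$sample_id))
    abort(sprintf("Sample sets differ between files (e.g. %s).",
                  paste(utils::head(missing, 3), collapse = ", ")),
          class = "kernaft_error_join")
  }
  surv <- surv[match(mat$sample_id, surv$sample_id), ]
  x <- as.matrix(mat[setdiff(names(mat), "sample_id")])
  if (any(surv$time <= 0)) {
    abort("Survival times must be positive.", class = "kernaft_error_time")
  }
  if (!all(surv$status %in% c(0, 1))) {
    abort("`status` must be 0/1.", class = "kernaft_error_status")
  }
  survival_dataset(x, surv$time, surv$status, sample_id = mat$sample_id)
}

#' Write a survival dataset to delimited files
#'
#' Inverse of [read_dataset()]: writes the covariate matrix (samples in rows,
#' `sample_id` first) and the survival table (`sample_id`, `time`, `status`).
#'
#' @param data A [survival_dataset()].
#' @param matrix_path,survival_path Output paths.
#' @param delim Field delimiter.
#' @return Invisibly, `data`.
#' @export
write_dataset <- function(data, matrix_path, survival_path, delim = "\t") {
  data <- as_survival_dataset(data)
  mat <- dplyr::bind_cols(tibble::tibble(sample_id = data$sample_id),
                          tibble::as_tibble(data$x))
  readr::write_delim(mat, matrix_path, delim = delim, progress = FALSE)
  readr::write_delim(
    tibble::tibble(sample_id = data$sample_id, time = data$time,
                   status = data$status),
    survival_path, delim = delim, progress = FALSE)
  invisible(data)
}

#' Write a simulated study to a directory
#'
#' Writes `<prefix>_{train,test}_{matrix,survival}.tsv` plus
#' `<prefix>_manifest.json` holding the full [simulation_config()] and the
#' true coefficient vector, so a simulated study is fully reproducible and
#' reloadable with [read_dataset()].
#'
#' @param sim An `aft_sim` from [make_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the manifest path.
#' @export
write_sim <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "aft_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(part) file.path(dir, paste0(prefix, "_", part, ".tsv"))
  write_dataset(sim$train, path("train_matrix"), path("train_survival"))
  write_dataset(sim$test, path("test_matrix"), path("test_survival"))
  manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
  cfg <- unclass(sim$config)
  jsonlite::write_json(
    list(config = cfg, truth = as.list(sim$truth[sim$truth != 0])),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
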