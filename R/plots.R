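# ggplot2 displays for the fitted objects and study results.

#' @method autoplot dkrr_fit
#' @export
autoplot.dkrr_fit <- function(object, ...) {
  d <- tidy(object)
  d$censoring <- factor(ifelse(d$status == 1, "event", "censored"),
                        c("event", "censored"))
  ggplot2::ggplot(d, ggplot2::aes(.data$log_time, .data$fitted,
                                  colour = .data$censoring)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "observed log time", y = "fitted log time",
                  colour = NULL,
                  title = sprintf("DKRR fit (%s kernel, lambda = %g)",
                                  object$spec$family, object$lambda)) +
    ggplot2::theme_minimal()
}

#' @method autoplot akrr_fit
#' @export
autoplot.akrr_fit <- function(object, ...) {
  d <- tidy(object, all = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(.data$index, .data$estimate,
                                  colour = .data$selected)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$index, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "feature index", y = "coefficient",
                  title = sprintf("AKRR coefficients (lambda = %g, p = %g)",
                                  object$lambda, object$p)) +
    ggplot2::theme_minimal()
}

#' @method autoplot akrr_replicates
#' @export
autoplot.akrr_replicates <- function(object, ...) {
  d <- object$frequency
  d$index <- factor(d$index)
  ggplot2::ggplot(d, ggplot2::aes(.data$index, 100 * .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "true variable (column index)",
                  y = "selection frequency (%)",
                  title = sprintf(
                    "Selection frequency over %d replicates (lambda = %g, p = %g)",
                    object$summary$n_replicates, object$summary$lambda,
                    object$summary$p)) +
    ggplot2::theme_minimal()
}

#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  g <- object$grid
  g$p <- factor(g$p)
  ggplot2::ggplot(g, ggplot2::aes(.data$lambda, .data$mean_rrmse,
                                  colour = .data$p, group = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lambda", y = "mean CV RRMSE", colour = "p",
                  title = "Cross-validation surface") +
    ggplot2::theme_minimal()
}

#' Kernel comparison plot
#'
#' Boxplots of test RRMSE by kernel and correlation from
#' [kernel_rrmse_study()] output, facetted by the signal power `k`.
#'
#' @param study Tibble from [kernel_rrmse_study()].
#' @return A ggplot object.
#' @export
plot_kernel_study <- function(study) {
  study$r <- factor(study$r)
  ggplot2::ggplot(study, ggplot2::aes(.data$r, .data$rrmse,
                                      fill = .data$kernel)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both,
                        scales = "free_y") +
    ggplot2::labs(x = "AR correlation r", y = "test RRMSE (events)") +
    ggplot2::theme_minimal()
}
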