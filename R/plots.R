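#' Plot a precision-recall curve
#'
#' @param object A `pr_result` from [pr_curve()].
#' @param ... Unused.
#' @return A ggplot: the step-wise PR curve with the AUPR in the title.
#' @export
autoplot.pr_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh", colour = "#2c7fb8") +
    ggplot2::geom_point(size = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      title = sprintf("Precision-recall curve (AUPR = %.3f)",
                      attr(object, "aupr"))) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation curve
#'
#' @param object A `wsgl_cv` from [cv_wsgl()].
#' @param ... Unused.
#' @return A ggplot of CV error vs lambda with one-SE bars and the
#'   selected lambda marked.
#' @export
autoplot.wsgl_cv <- function(object, ...) {
  df <- tidy(object)
  best <- attr(object, "best_lambda")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$cv_error)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$cv_error - .data$cv_se,
                   ymax = .data$cv_error + .data$cv_se),
      width = 0, colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(colour = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed") +
    ggplot2::labs(x = expression(lambda), y = "CV mean squared error",
                  title = sprintf("Cross-validation (best lambda = %g)",
                                  best)) +
    ggplot2::theme_minimal()
}

#' Plot fitted coefficients by group
#'
#' @param object A `wsgl_fit`.
#' @param ... Unused.
#' @return A ggplot stem plot of standardized coefficients coloured by
#'   group membership of the active groups.
#' @export
autoplot.wsgl_fit <- function(object, ...) {
  df <- tidy(object)
  df$index <- seq_len(nrow(df))
  df$active_group <- ifelse(df$group_id %in%
                              names(object$group_norms)[object$group_norms > 0],
                            df$group_id, NA_character_)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index,
                                   y = .data$beta_standardized)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$index, yend = 0,
                                       colour = .data$active_group),
                          show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Locus index", y = "Standardized coefficient",
                  title = sprintf(
                    "%d nonzero loci in %d groups (lambda = %g, alpha = %g)",
                    sum(df$beta_standardized != 0),
                    sum(object$group_norms > 0),
                    object$lambda, object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot a method comparison table
#'
#' @param results Tibble from [compare_methods()].
#' @return A ggplot of AUPR against lambda, one line per estimator.
#' @export
plot_method_comparison <- function(results) {
  stopifnot(all(c("method", "lambda", "aupr") %in% names(results)))
  ggplot2::ggplot(results, ggplot2::aes(x = .data$lambda, y = .data$aupr,
                                        colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(lambda), y = "AUPR", colour = NULL) +
    ggplot2::theme_minimal()
}
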