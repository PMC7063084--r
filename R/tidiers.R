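#' Tidy a fitted model into a per-locus tibble
#'
#' @param x A `wsgl_fit`.
#' @param ... Unused.
#' @return Tibble with `locus_id`, `group_id`, `omega`,
#'   `beta_standardized`, `beta_original`.
#' @export
tidy.wsgl_fit <- function(x, ...) {
  tibble::tibble(
    locus_id = names(x$beta),
    group_id = x$group_labels[x$group_index],
    omega = unname(x$weights),
    beta_standardized = unname(x$beta_std),
    beta_original = unname(x$beta)
  )
}

#' One-row summary of a fitted model
#'
#' @param x A `wsgl_fit`.
#' @param ... Unused.
#' @return Tibble with sample/locus counts, hyperparameters, support
#'   sizes, the final objective value and convergence information.
#' @export
glance.wsgl_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = x$p, n_groups = length(x$group_labels),
    lambda = x$lambda, alpha = x$alpha,
    n_nonzero = sum(x$beta != 0),
    n_active_groups = sum(x$group_norms > 0),
    objective = x$objective_trace[length(x$objective_trace)],
    n_iter = x$n_iter, converged = x$converged
  )
}

#' @export
tidy.wsgl_cv <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("lambda", "cv_error", "cv_se")])
}

#' @export
glance.wsgl_cv <- function(x, ...) {
  best <- attr(x, "best_lambda")
  tibble::tibble(
    best_lambda = best,
    cv_error = x$cv_error[match(best, x$lambda)],
    k_folds = attr(x, "k_folds"),
    alpha = attr(x, "alpha")
  )
}

#' @export
tidy.pr_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("threshold", "recall", "precision")])
}

#' @export
glance.pr_result <- function(x, ...) {
  tibble::tibble(aupr = attr(x, "aupr"), n_pos = attr(x, "n_pos"),
                 n = attr(x, "n"))
}

#' @export
tidy.qc_report <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("n_input_loci", "n_removed_maf",
                                 "n_removed_missing", "n_removed_hwe",
                                 "n_kept")])
}
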