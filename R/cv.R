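#' Cross-validated lambda selection
#'
#' k-fold cross-validation of the held-out mean squared prediction error
#' over a lambda grid. Fold assignment is fixed by `seed`; standardization
#' statistics are computed on the training folds only (each fold's model
#' is refit from scratch by [fit_wsgl()], which standardizes internally).
#' The default grid is \eqn{\lambda \in \{0.01, 0.02, \dots, 0.10\}}.
#' `best_lambda` is the grid value minimizing the CV error, with ties
#' broken toward the smallest lambda (less sparsity at equal error).
#'
#' @inheritParams fit_wsgl
#' @param lambda_grid Candidate lambda values. Default
#'   `seq(0.01, 0.1, by = 0.01)`.
#' @param k_folds Number of folds (>= 2). Default 5.
#' @param seed Integer seed fixing the fold assignment.
#' @param ... Passed on to [fit_wsgl()].
#' @return A `wsgl_cv` object: tibble of `lambda`, `cv_error`, `cv_se`
#'   (one row per grid value) with attributes `best_lambda`, `k_folds`,
#'   `alpha`. [tidy()] returns the table, [glance()] the selection.
#' @export
cv_wsgl <- function(X, y, groups, alpha = 0.95, weights = NULL,
                    lambda_grid = seq(0.01, 0.1, by = 0.01),
                    k_folds = 5L, seed = NULL, ...) {
  X <- as_design_matrix(X)
  y <- check_phenotype(y, X)
  grp <- as_group_index(groups, X)
  w <- resolve_weights(weights, X)
  n <- nrow(X)
  if (k_folds < 2L) stop("`k_folds` must be at least 2", call. = FALSE)
  if (n < k_folds) stop("need at least one sample per fold", call. = FALSE)
  lambda_grid <- sort(unique(as.numeric(lambda_grid)))
  if (any(lambda_grid < 0)) stop("lambda grid must be nonnegative", call. = FALSE)

  folds <- with_local_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  fold_err <- matrix(NA_real_, k_folds, length(lambda_grid))
  for (f in seq_len(k_folds)) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]
    # a column constant within the training fold cannot be standardized;
    # drop it for this fold only
    keep <- apply(Xtr, 2L, function(col) stats::var(col) > 0)
    if (!all(keep)) {
      warning(sum(!keep), " zero-variance column(s) dropped in fold ", f,
              call. = FALSE)
    }
    for (li in seq_along(lambda_grid)) {
      fit <- fit_wsgl(Xtr[, keep, drop = FALSE], y[!test],
                      grp$index[keep], lambda = lambda_grid[li],
                      alpha = alpha, weights = w[keep], ...)
      pred <- predict(fit, X[test, keep, drop = FALSE])
      fold_err[f, li] <- mean((y[test] - pred)^2)
    }
  }
  cv_error <- colMeans(fold_err)
  cv_se <- apply(fold_err, 2L, stats::sd) / sqrt(k_folds)
  best <- lambda_grid[which.min(cv_error)]

  structure(tibble::tibble(
    lambda = lambda_grid,
    cv_error = cv_error,
    cv_se = cv_se
  ), best_lambda = best, k_folds = k_folds, alpha = alpha,
     class = c("wsgl_cv", "tbl_df", "tbl", "data.frame"))
}

#' Selection frequency of loci under subsampling
#'
#' Stability-selection-style locus scores: the model is refit on
#' `n_repeats` random subsamples (drawn without replacement), and each
#' locus is scored by the fraction of fits in which its coefficient is
#' nonzero. The score lies in `[0, 1]` and serves as the per-locus
#' "predicted probability" of association in precision-recall evaluation.
#'
#' @inheritParams fit_wsgl
#' @param n_repeats Number of subsampled fits. Default 100.
#' @param subsample_fraction Fraction of samples per subsample, in (0, 1].
#'   Default 0.5.
#' @param seed Integer seed fixing the subsamples.
#' @return A `selection_freq` tibble with columns `locus_id`, `group`,
#'   `freq`; attribute `n_repeats`.
#' @export
selection_frequency <- function(X, y, groups, lambda, alpha = 0.95,
                                weights = NULL, n_repeats = 100L,
                                subsample_fraction = 0.5, seed = NULL, ...) {
  X <- as_design_matrix(X)
  y <- check_phenotype(y, X)
  grp <- as_group_index(groups, X)
  w <- resolve_weights(weights, X)
  if (n_repeats < 1L) stop("`n_repeats` must be >= 1", call. = FALSE)
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop("`subsample_fraction` must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(X)
  nsub <- floor(subsample_fraction * n)
  if (nsub < 2L) stop("subsample would have fewer than 2 samples", call. = FALSE)

  counts <- numeric(ncol(X))
  with_local_seed(seed, {
    for (rep in seq_len(n_repeats)) {
      idx <- if (nsub == n) seq_len(n) else sort(sample.int(n, nsub))
      Xs <- X[idx, , drop = FALSE]
      keep <- apply(Xs, 2L, function(col) stats::var(col) > 0)
      fit <- fit_wsgl(Xs[, keep, drop = FALSE], y[idx], grp$index[keep],
                      lambda = lambda, alpha = alpha, weights = w[keep], ...)
      counts[keep] <- counts[keep] + (fit$beta != 0)
    }
  })

  structure(tibble::tibble(
    locus_id = colnames(X),
    group = grp$labels[grp$index],
    freq = counts / n_repeats
  ), n_repeats = n_repeats, lambda = lambda, alpha = alpha,
     class = c("selection_freq", "tbl_df", "tbl", "data.frame"))
}
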