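#' Fit the weighted sparse group lasso
#'
#' Solves
#' \deqn{\min_\beta \frac{1}{2n}\|y - X\beta\|_2^2 +
#'   (1-\alpha)\lambda\sum_l \sqrt{p_l}\|\beta^{(l)}\|_2 +
#'   \alpha\lambda\sum_j \omega_j|\beta_j|}
#' by block coordinate descent: groups are swept in ascending index order,
#' each group is first screened against the group-zero condition, and
#' surviving groups are solved by cyclic per-locus updates. Columns of `X`
#' are centered and scaled to unit variance internally and `y` is centered
#' (the intercept is absorbed by centering and never penalized);
#' coefficients are reported on both scales. Thresholded coefficients are
#' stored as exact zeros, so the selected support can be read directly from
#' `beta != 0`.
#'
#' @param X Genotype/design matrix (n samples x p loci). Columns must have
#'   nonzero variance and no missing entries; run [apply_qc()] first for
#'   raw genotype panels.
#' @param y Numeric phenotype vector of length n (rows aligned with `X`).
#' @param groups Group (gene) assignment: a vector of length p, or a
#'   two-column data frame (locus_id, group_id) matched against
#'   `colnames(X)`.
#' @param lambda Overall regularization strength \eqn{\lambda \ge 0}.
#' @param alpha Mixing ratio \eqn{\alpha \in [0,1]} between the l1
#'   (`alpha = 1`) and group l2 (`alpha = 0`) penalties. Default 0.95.
#' @param weights Per-locus l1 weights \eqn{\omega}. `NULL` (default)
#'   derives \eqn{\omega_j = 2\,\mathrm{MAF}_j(1-\mathrm{MAF}_j)} from the
#'   dosage matrix; pass `1` for the unweighted estimator or a vector for
#'   custom weights.
#' @param standardize If `TRUE` (default), scale centered columns to unit
#'   variance so every locus is penalized on a common scale. With `FALSE`
#'   columns are centered only, keeping each locus on its dosage scale
#'   \eqn{x_j^\top x_j/n \approx 2f_j(1-f_j) = \omega_j}; on that scale
#'   the MAF weights make the l1 selection threshold invariant to allele
#'   frequency for a given per-allele effect, which is the regime the
#'   weighted estimator is designed for. Use `FALSE` when comparing the
#'   weighted and unweighted estimators on dosage data.
#' @param normalize_weights If `TRUE`, rescale `weights` to mean 1 so
#'   lambda grids stay comparable with the unweighted fit. Default `FALSE`.
#' @param tol_coef,tol_obj Convergence: stop when the largest absolute
#'   coefficient change is below `tol_coef` and the relative objective
#'   change below `tol_obj`.
#' @param tol_kkt Convergence is only declared once the largest
#'   subgradient (KKT) violation is below this certificate tolerance, so
#'   a fit flagged `converged` is a verified optimum.
#' @param max_iter Maximum outer sweeps; non-convergence is flagged, not
#'   an error.
#' @return An object of class `wsgl_fit`: coefficients on the original
#'   (`beta`) and standardized (`beta_std`) scales, `intercept`, per-group
#'   norms, the per-sweep objective trace, iteration count and convergence
#'   flag. Use [tidy()] for a per-locus tibble and [glance()] for a
#'   one-row summary.
#' @examples
#' sim <- simulate_gwas(sim_design(n_samples = 60, n_loci = 40,
#'                                 n_groups = 8, n_causal = 4,
#'                                 n_causal_groups = 2, seed = 1))
#' fit <- fit_wsgl(sim$genotype, sim$phenotype, sim$groups, lambda = 0.09)
#' sum(fit$beta != 0)
#' @seealso [fit_lasso()], [fit_group_lasso()], [fit_sgl()], [cv_wsgl()],
#'   [kkt_check()]
#' @export
fit_wsgl <- function(X, y, groups, lambda, alpha = 0.95, weights = NULL,
                     standardize = TRUE, normalize_weights = FALSE,
                     tol_coef = 1e-5, tol_obj = 1e-8, tol_kkt = 1e-6,
                     max_iter = 1000L) {
  X <- as_design_matrix(X)
  if (anyNA(X)) {
    stop("`X` contains missing entries; impute (see apply_qc()) before fitting",
         call. = FALSE)
  }
  y <- check_phenotype(y, X)
  check_hyper(lambda, alpha)
  grp <- as_group_index(groups, X)
  w <- resolve_weights(weights, X)
  if (normalize_weights) w <- w / mean(w)

  std <- standardize_design(X, standardize = standardize)
  ybar <- mean(y)
  yc <- y - ybar

  res <- .wsgl_bcd(std$X, yc, grp$index - 1L, grp$m, w, alpha, lambda,
                   tol_coef, tol_obj, tol_kkt, as.integer(max_iter), 10000L)
  beta_std <- as.vector(res$beta)
  beta <- beta_std / std$scale
  group_norms <- vapply(split(beta_std, grp$index),
                        function(b) sqrt(sum(b^2)), 0)
  names(group_norms) <- grp$labels
  names(beta) <- names(beta_std) <- colnames(X)

  structure(list(
    beta = beta,
    beta_std = beta_std,
    intercept = ybar - sum(beta * std$center),
    group_norms = group_norms,
    objective_trace = as.numeric(res$objective_trace),
    n_iter = res$n_iter,
    converged = res$converged,
    lambda = lambda,
    alpha = alpha,
    weights = stats::setNames(w, colnames(X)),
    group_index = grp$index,
    group_labels = grp$labels,
    center = std$center,
    scale = std$scale,
    y_center = ybar,
    standardize = standardize,
    n = nrow(X),
    p = ncol(X)
  ), class = "wsgl_fit")
}

#' Lasso, group lasso and sparse group lasso fits
#'
#' Exact special cases of [fit_wsgl()]: the lasso is `alpha = 1` with unit
#' weights, the group lasso `alpha = 0`, and the sparse group lasso keeps
#' `alpha` free with unit weights. All share the `1/(2n)` loss scaling so
#' `lambda` is comparable across the four estimators.
#'
#' @inheritParams fit_wsgl
#' @param ... Passed on to [fit_wsgl()] (tolerances, `max_iter`).
#' @return A `wsgl_fit` object.
#' @export
fit_lasso <- function(X, y, groups = NULL, lambda, ...) {
  if (is.null(groups)) groups <- rep(1L, ncol(as_design_matrix(X)))
  fit_wsgl(X, y, groups, lambda = lambda, alpha = 1, weights = 1, ...)
}

#' @rdname fit_lasso
#' @export
fit_group_lasso <- function(X, y, groups, lambda, ...) {
  fit_wsgl(X, y, groups, lambda = lambda, alpha = 0, weights = 1, ...)
}

#' @rdname fit_lasso
#' @export
fit_sgl <- function(X, y, groups, lambda, alpha = 0.95, ...) {
  fit_wsgl(X, y, groups, lambda = lambda, alpha = alpha, weights = 1, ...)
}

#' @export
#' @method print wsgl_fit
print.wsgl_fit <- function(x, ...) {
  kind <- if (all(x$weights == 1)) {
    if (x$alpha == 1) "lasso" else if (x$alpha == 0) "group lasso"
    else "sparse group lasso"
  } else "weighted sparse group lasso"
  cat(sprintf(
    "<wsgl_fit> %s | n = %d, p = %d, %d groups\n", kind, x$n, x$p,
    length(x$group_labels)))
  cat(sprintf("  lambda = %g, alpha = %g\n", x$lambda, x$alpha))
  cat(sprintf("  nonzero loci: %d in %d groups | %s after %d sweeps\n",
              sum(x$beta != 0), sum(x$group_norms > 0),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Predict phenotype values from a fitted model
#'
#' @param object A `wsgl_fit`.
#' @param newdata Matrix or data frame with the model's loci as columns
#'   (original dosage scale).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.wsgl_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(names(object$beta) %in% colnames(newdata))) {
    newdata <- newdata[, names(object$beta), drop = FALSE]
  }
  if (ncol(newdata) != object$p) {
    stop("`newdata` must have the model's ", object$p, " loci", call. = FALSE)
  }
  as.vector(newdata %*% object$beta) + object$intercept
}

#' @export
#' @method coef wsgl_fit
coef.wsgl_fit <- function(object, standardized = FALSE, ...) {
  if (standardized) object$beta_std else object$beta
}
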