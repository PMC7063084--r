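#' KKT optimality check for a (weighted) sparse group lasso solution
#'
#' Certifies a coefficient vector against the subgradient optimality
#' conditions of the objective. For a zero group the condition is
#' \eqn{\|S(X^{(k)\top} r/n,\ \alpha\lambda\omega^{(k)})\|_2 \le
#' \sqrt{p_k}(1-\alpha)\lambda}; for a nonzero coordinate, stationarity
#' \eqn{x_i^\top r/n = \sqrt{p_k}(1-\alpha)\lambda\,
#' \beta_i/\|\beta^{(k)}\|_2 + \alpha\lambda\omega_i\,\mathrm{sign}(\beta_i)};
#' for a zero coordinate inside a nonzero group,
#' \eqn{|x_i^\top r/n| \le \alpha\lambda\omega_i}. Here \eqn{r = y - X\beta}
#' is the full residual. Inputs are used exactly as supplied (no internal
#' standardization), so pass the same scale the solution was computed on —
#' [kkt_check_fit()] does this for a [fit_wsgl()] result.
#'
#' @inheritParams wsgl_objective
#' @param beta Coefficient vector to certify (same scale as `X`, `y`).
#' @param tol Tolerance on the violation measures. Default `1e-5`.
#' @return A `kkt_report`: tibble with `max_group_violation`,
#'   `max_coord_violation` and `satisfied`.
#' @export
kkt_check <- function(X, y, groups, beta, lambda, alpha = 0.95, weights = 1,
                      tol = 1e-5) {
  X <- as_design_matrix(X)
  y <- check_phenotype(y, X)
  check_hyper(lambda, alpha)
  grp <- as_group_index(groups, X)
  w <- resolve_weights(weights, X)
  if (length(beta) != ncol(X)) stop("`beta` must have length p", call. = FALSE)
  n <- nrow(X)
  r <- y - as.vector(X %*% beta)
  g <- as.vector(crossprod(X, r)) / n

  group_viol <- 0
  coord_viol <- 0
  for (k in seq_len(grp$m)) {
    idx <- which(grp$index == k)
    bk <- beta[idx]
    pk <- length(idx)
    bnd <- sqrt(pk) * (1 - alpha) * lambda
    gn <- sqrt(sum(bk^2))
    if (gn == 0) {
      s <- soft_threshold(g[idx], alpha * lambda * w[idx])
      group_viol <- max(group_viol, sqrt(sum(s^2)) - bnd)
    } else {
      for (j in seq_along(idx)) {
        i <- idx[j]
        if (bk[j] != 0) {
          resid <- g[i] - bnd * bk[j] / gn - alpha * lambda * w[i] * sign(bk[j])
          coord_viol <- max(coord_viol, abs(resid))
        } else {
          coord_viol <- max(coord_viol, abs(g[i]) - alpha * lambda * w[i])
        }
      }
    }
  }
  group_viol <- max(group_viol, 0)
  coord_viol <- max(coord_viol, 0)
  structure(tibble::tibble(
    max_group_violation = group_viol,
    max_coord_violation = coord_viol,
    tol = tol,
    satisfied = group_viol <= tol && coord_viol <= tol
  ), class = c("kkt_report", "tbl_df", "tbl", "data.frame"))
}

#' @rdname kkt_check
#' @param fit A `wsgl_fit` object.
#' @export
kkt_check_fit <- function(fit, X, y, tol = 1e-5) {
  stopifnot(inherits(fit, "wsgl_fit"))
  X <- as_design_matrix(X)
  Xs <- sweep(sweep(X, 2L, fit$center, "-"), 2L, fit$scale, "/")
  yc <- check_phenotype(y, X) - fit$y_center
  kkt_check(Xs, yc, fit$group_index, fit$beta_std, fit$lambda, fit$alpha,
            fit$weights, tol = tol)
}
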