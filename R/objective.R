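#' Soft-threshold operator
#'
#' The proximal map of the l1 penalty,
#' \eqn{S(a, b)_j = \mathrm{sign}(a_j)(|a_j| - b_j)_+}, applied elementwise.
#'
#' @param a Numeric vector.
#' @param b Nonnegative threshold, scalar or a vector conformable with `a`.
#' @return Numeric vector of the same length as `a`.
#' @examples
#' soft_threshold(c(3, -0.5, -3), 1)
#' @export
soft_threshold <- function(a, b) {
  if (any(!is.finite(b)) || any(b < 0)) {
    stop("threshold `b` must be nonnegative (invalid penalty)", call. = FALSE)
  }
  if (length(b) != 1L && length(b) != length(a)) {
    stop("`a` and `b` are not conformable", call. = FALSE)
  }
  sign(a) * pmax(abs(a) - b, 0)
}

#' Weighted sparse group lasso objective
#'
#' Evaluates
#' \eqn{\frac{1}{2n}\|y - X\beta\|_2^2 +
#'   (1-\alpha)\lambda\sum_l \sqrt{p_l}\|\beta^{(l)}\|_2 +
#'   \alpha\lambda\sum_j \omega_j|\beta_j|}
#' at a given coefficient vector, on the scale of the inputs as supplied
#' (no internal standardization). With `weights = 1` this is the sparse
#' group lasso objective; with `lambda = 0` the pure least-squares loss.
#'
#' @param X Design matrix (n x p).
#' @param y Response vector of length n.
#' @param groups Group assignment: vector of length p or a two-column
#'   locus/group data frame.
#' @param beta Coefficient vector of length p.
#' @param lambda Regularization strength, >= 0.
#' @param alpha Mixing ratio in `[0, 1]` between the l1 (`alpha = 1`) and
#'   group l2 (`alpha = 0`) penalties.
#' @param weights Per-locus l1 penalty weights \eqn{\omega}; scalar recycled.
#' @return The objective value (a single number).
#' @export
wsgl_objective <- function(X, y, groups, beta, lambda, alpha = 0.95,
                           weights = 1) {
  X <- as_design_matrix(X)
  y <- check_phenotype(y, X)
  check_hyper(lambda, alpha)
  if (length(beta) != ncol(X)) stop("`beta` must have length p", call. = FALSE)
  grp <- as_group_index(groups, X)
  w <- resolve_weights(weights, X)
  n <- nrow(X)
  r <- y - as.vector(X %*% beta)
  gnorm <- vapply(split(beta, grp$index), function(b) sqrt(sum(b^2)), 0)
  pl <- tabulate(grp$index, nbins = grp$m)
  sum(r^2) / (2 * n) +
    (1 - alpha) * lambda * sum(sqrt(pl) * gnorm) +
    alpha * lambda * sum(w * abs(beta))
}

#' Group-zero screening condition
#'
#' Tests whether an entire group's coefficients are set to zero in the
#' current block-coordinate sweep:
#' \eqn{\|S(X^{(k)\top}\gamma^{(-k)}/n, \alpha\lambda\omega^{(k)})\|_2
#'   \le \sqrt{p_k}\,(1-\alpha)\lambda},
#' where \eqn{\gamma^{(-k)}} is the residual of `y` with every other
#' group's contribution removed.
#'
#' @param Xk Design block of group k (n x p_k).
#' @param partial_residual The n-vector \eqn{\gamma^{(-k)}}.
#' @param lambda,alpha Hyperparameters (see [wsgl_objective()]).
#' @param weights Weights \eqn{\omega^{(k)}} for the loci of group k.
#' @return `TRUE` if the whole group is zeroed.
#' @export
group_is_zero <- function(Xk, partial_residual, lambda, alpha = 0.95,
                          weights = 1) {
  Xk <- as.matrix(Xk)
  check_hyper(lambda, alpha)
  if (length(partial_residual) != nrow(Xk)) {
    stop("partial residual length does not match `Xk`", call. = FALSE)
  }
  pk <- ncol(Xk)
  if (length(weights) == 1L) weights <- rep(weights, pk)
  n <- nrow(Xk)
  g <- crossprod(Xk, partial_residual) / n
  s <- soft_threshold(as.vector(g), alpha * lambda * weights)
  sqrt(sum(s^2)) <= sqrt(pk) * (1 - alpha) * lambda + 1e-12
}

#' Single coordinate update
#'
#' The per-locus update inside a surviving group:
#' \deqn{\hat\beta_i = \frac{S(x_i^\top\gamma^{(-k,i)}/n,\ \alpha\lambda\omega_i)}
#'   {x_i^\top x_i/n + (1-\alpha)\lambda / \|\hat\beta^{(k)}\|_2}}
#' where \eqn{\gamma^{(-k,i)}} is the residual excluding locus i's own
#' contribution. The coefficient is zero exactly when
#' \eqn{|x_i^\top\gamma^{(-k,i)}| \le n\alpha\lambda\omega_i}.
#'
#' @param xi Column of locus i (length n).
#' @param partial_residual The n-vector \eqn{\gamma^{(-k,i)}}.
#' @param group_norm Current group norm \eqn{\|\hat\beta^{(k)}\|_2} (must be
#'   positive when `alpha < 1` and `lambda > 0`); ignored when the group
#'   term vanishes.
#' @param lambda,alpha Hyperparameters.
#' @param weight The locus weight \eqn{\omega_i}.
#' @return The updated coefficient (a single number).
#' @export
coordinate_update <- function(xi, partial_residual, group_norm, lambda,
                              alpha = 0.95, weight = 1) {
  check_hyper(lambda, alpha)
  n <- length(xi)
  d <- sum(xi^2) / n
  if (d <= .Machine$double.eps) {
    stop("zero-variance column; standardize/QC the design first",
         call. = FALSE)
  }
  z <- sum(xi * partial_residual) / n
  num <- soft_threshold(z, alpha * lambda * weight)
  l2 <- (1 - alpha) * lambda
  if (l2 > 0) {
    if (!is.numeric(group_norm) || group_norm <= 0) {
      stop("`group_norm` must be positive when the group penalty is active",
           call. = FALSE)
    }
    return(as.numeric(num / (d + l2 / group_norm)))
  }
  as.numeric(num / d)
}

#' Smallest lambda with an all-zero fit
#'
#' Computes the smallest regularization strength at which the all-zero
#' coefficient vector satisfies the group-zero condition for every group,
#' evaluated at the full residual `y` on the same (standardized or
#' centered-only) scale [fit_wsgl()] uses. For `lambda >= lambda_max` the
#' fit is exactly zero.
#'
#' @inheritParams wsgl_objective
#' @param standardize Must match the `standardize` setting of the fit the
#'   bound is used with (see [fit_wsgl()]).
#' @return A single nonnegative number.
#' @export
lambda_max <- function(X, y, groups, alpha = 0.95, weights = 1,
                       standardize = TRUE) {
  X <- as_design_matrix(X)
  y <- check_phenotype(y, X)
  check_hyper(1, alpha)
  grp <- as_group_index(groups, X)
  w <- resolve_weights(weights, X)
  std <- standardize_design(X, standardize = standardize)
  yc <- y - mean(y)
  n <- nrow(X)
  g <- as.vector(crossprod(std$X, yc)) / n

  lam_group <- function(k) {
    idx <- which(grp$index == k)
    gk <- g[idx]
    wk <- w[idx]
    pk <- length(idx)
    if (alpha >= 1) return(max(abs(gk) / wk))
    # zero condition holds iff ||S(g, a*lam*w)|| <= sqrt(pk)(1-a)lam;
    # LHS decreases and RHS increases in lam, so bisect
    holds <- function(lam) {
      s <- soft_threshold(gk, alpha * lam * wk)
      sqrt(sum(s^2)) <= sqrt(pk) * (1 - alpha) * lam
    }
    hi <- max(abs(gk) / (alpha * wk))
    if (hi == 0) return(0)
    lo <- 0
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (holds(mid)) hi <- mid else lo <- mid
      if (hi - lo < 1e-12 * max(1, hi)) break
    }
    hi
  }
  if (alpha <= 0) {
    # RHS uses (1-alpha); fold into the group formula
    return(max(vapply(seq_len(grp$m), function(k) {
      idx <- which(grp$index == k)
      sqrt(sum(g[idx]^2)) / (sqrt(length(idx)) * (1 - alpha))
    }, 0)))
  }
  max(vapply(seq_len(grp$m), lam_group, 0))
}
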