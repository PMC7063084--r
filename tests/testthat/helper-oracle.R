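# Independent oracles, kept deliberately separate from the package's
# solver: a proximal-gradient minimizer of the same convex objective, a
# brute-force precision-recall integrator, and small random instances.

# Standardize columns with the 1/n convention (matches the fit contract).
std_design <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  s <- sqrt(colSums(Xc^2) / nrow(X))
  sweep(Xc, 2L, s, "/")
}

oracle_objective <- function(Xs, yc, groups, beta, lambda, alpha, w) {
  n <- nrow(Xs)
  r <- yc - as.vector(Xs %*% beta)
  gn <- tapply(beta, groups, function(b) sqrt(sum(b^2)))
  pl <- as.vector(table(groups))
  sum(r^2) / (2 * n) + (1 - alpha) * lambda * sum(sqrt(pl) * gn) +
    alpha * lambda * sum(w * abs(beta))
}

# ISTA on the standardized problem. The prox of the sparse-group penalty
# is coordinate soft-thresholding followed by the group-wise l2 prox.
oracle_wsgl <- function(Xs, yc, groups, lambda, alpha, w,
                        max_iter = 100000L, tol = 1e-13) {
  n <- nrow(Xs)
  p <- ncol(Xs)
  L <- max(eigen(crossprod(Xs) / n, only.values = TRUE)$values)
  step <- 1 / L
  gidx <- split(seq_len(p), groups)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    grad <- -as.vector(crossprod(Xs, yc - Xs %*% beta)) / n
    b <- beta - step * grad
    b <- sign(b) * pmax(abs(b) - step * alpha * lambda * w, 0)
    for (idx in gidx) {
      gn <- sqrt(sum(b[idx]^2))
      bnd <- step * (1 - alpha) * lambda * sqrt(length(idx))
      b[idx] <- if (gn <= bnd) 0 else b[idx] * (1 - bnd / gn)
    }
    if (max(abs(b - beta)) < tol) {
      beta <- b
      break
    }
    beta <- b
  }
  beta
}

# AUPR by exhaustive enumeration of every distinct score cutoff, counting
# TP/FP directly at each.
oracle_aupr <- function(scores, labels) {
  labels <- as.integer(labels)
  cuts <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  area <- 0
  prev_recall <- 0
  for (cut in cuts) {
    sel <- scores >= cut
    tp <- sum(labels[sel] == 1L)
    fp <- sum(labels[sel] == 0L)
    precision <- tp / (tp + fp)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Random group-structured regression instance with MAF-derived weights.
rand_instance <- function(seed, n = NULL, p = NULL, m = NULL) {
  set.seed(seed)
  n <- if (is.null(n)) sample(20:50, 1) else n
  p <- if (is.null(p)) sample(10:40, 1) else p
  m <- if (is.null(m)) sample(2:6, 1) else m
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("l", seq_len(p))
  groups <- sort(sample(seq_len(m), p, replace = TRUE))
  groups[seq_len(m)] <- seq_len(m)  # every group nonempty
  groups <- sort(groups)
  beta <- numeric(p)
  nz <- sample(seq_len(p), max(2, p %/% 5))
  beta[nz] <- rnorm(length(nz), 0, 1.5)
  y <- as.vector(X %*% beta) + rnorm(n)
  maf <- runif(p, 0.01, 0.5)
  list(X = X, y = y, groups = groups, w = 2 * maf * (1 - maf), maf = maf)
}
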