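# Internal helpers shared across the fitting, CV and simulation code.

# Coerce a genotype/design input to a plain numeric matrix with locus ids.
as_design_matrix <- function(X, arg = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("`", arg, "` must be a numeric matrix or data frame", call. = FALSE)
  }
  if (nrow(X) < 2L) stop("`", arg, "` needs at least 2 samples", call. = FALSE)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("locus_", seq_len(ncol(X)))
  }
  if (anyDuplicated(colnames(X))) {
    stop("locus ids (column names of `", arg, "`) must be unique",
         call. = FALSE)
  }
  X
}

# Normalize a group specification to an integer code per column of X plus
# labels. Accepts a vector (factor/character/integer) of length p, or a
# two-column data frame (locus_id, group_id) matched by locus id.
as_group_index <- function(groups, X) {
  p <- ncol(X)
  if (is.data.frame(groups)) {
    if (ncol(groups) < 2L) {
      stop("a group data frame needs columns locus_id and group_id",
           call. = FALSE)
    }
    idx <- match(colnames(X), as.character(groups[[1L]]))
    if (anyNA(idx)) {
      stop("loci missing from the group map: ",
           paste(head(colnames(X)[is.na(idx)], 5L), collapse = ", "),
           call. = FALSE)
    }
    groups <- groups[[2L]][idx]
  }
  if (length(groups) != p) {
    stop("`groups` must assign every locus to exactly one group",
         call. = FALSE)
  }
  if (anyNA(groups)) stop("`groups` contains missing assignments", call. = FALSE)
  f <- factor(groups, levels = unique(groups))
  list(index = as.integer(f), labels = levels(f), m = nlevels(f))
}

# Center columns and (optionally) scale to unit variance with the 1/n
# convention, so x_j'x_j/n = 1 for every standardized column. With
# standardize = FALSE columns are centered only, keeping x_j'x_j/n at the
# dosage variance 2f(1-f) -- the scale on which the MAF weights equalize
# per-allele detectability. Zero-variance columns are a contract
# violation upstream of fitting.
standardize_design <- function(X, standardize = TRUE) {
  n <- nrow(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center, "-")
  scale <- sqrt(colSums(Xc^2) / n)
  bad <- scale <= .Machine$double.eps^0.5
  if (any(bad)) {
    stop("zero-variance column(s): ",
         paste(head(colnames(X)[bad], 5L), collapse = ", "),
         "; run QC / drop monomorphic loci before fitting", call. = FALSE)
  }
  if (!standardize) {
    return(list(X = Xc, center = center, scale = rep(1, ncol(X))))
  }
  list(X = sweep(Xc, 2L, scale, "/"), center = center, scale = scale)
}

check_phenotype <- function(y, X) {
  if (is.data.frame(y)) y <- y[[ncol(y)]]
  y <- as.numeric(y)
  if (length(y) != nrow(X)) {
    stop("phenotype length (", length(y), ") does not match sample count (",
         nrow(X), ")", call. = FALSE)
  }
  if (!all(is.finite(y))) stop("phenotype contains non-finite values", call. = FALSE)
  y
}

check_hyper <- function(lambda, alpha) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0) {
    stop("`lambda` must be a single value >= 0", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

# Resolve penalty weights for a design. NULL: derive from MAF when X is a
# dosage matrix, otherwise demand explicit weights. A scalar is recycled.
resolve_weights <- function(weights, X) {
  p <- ncol(X)
  if (is.null(weights)) {
    vals <- X[is.finite(X)]
    if (length(vals) && all(vals >= 0 & vals <= 2)) {
      return(maf_weights(compute_maf(X)))
    }
    stop("`weights` is NULL and `X` is not a 0..2 dosage matrix; ",
         "supply per-locus weights (e.g. maf_weights()) or 1 for unweighted",
         call. = FALSE)
  }
  if (length(weights) == 1L) weights <- rep(as.numeric(weights), p)
  weights <- as.numeric(weights)
  if (length(weights) != p) {
    stop("`weights` must have one entry per locus", call. = FALSE)
  }
  if (!all(is.finite(weights)) || any(weights <= 0)) {
    stop("penalty weights must be positive and finite", call. = FALSE)
  }
  weights
}

# Restore RNG state on exit so seeded helpers do not perturb the caller.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
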