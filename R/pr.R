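#' Precision-recall curve and AUPR
#'
#' Treats locus detection as binary classification under class imbalance:
#' causal loci carry label 1, all others 0, and each locus is scored
#' (e.g. by its [selection_frequency()]). The curve is traced over
#' descending score thresholds with tied scores grouped into a single
#' threshold; the area is the step-wise average-precision sum
#' \eqn{\sum_k (R_k - R_{k-1}) P_k} (linear PR interpolation is biased, so
#' it is not used).
#'
#' @param scores Numeric score per locus (higher = more likely causal).
#' @param labels 0/1 (or logical) causal labels, same length.
#' @return A `pr_result` tibble of threshold points (`threshold`,
#'   `recall`, `precision`) with attribute `aupr`; [glance()] extracts
#'   the area.
#' @examples
#' pr <- pr_curve(c(0.9, 0.5, 0.1), c(1, 0, 1))
#' attr(pr, "aupr")
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n_pos <- sum(labels)
  if (n_pos == 0L) {
    stop("no positive labels: AUPR is undefined", call. = FALSE)
  }

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # one threshold per distinct score value
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[last]
  fp <- cumsum(1L - l)[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos

  aupr <- sum(diff(c(0, recall)) * precision)
  structure(tibble::tibble(
    threshold = s[last],
    recall = recall,
    precision = precision
  ), aupr = aupr, n_pos = n_pos, n = length(labels),
     class = c("pr_result", "tbl_df", "tbl", "data.frame"))
}

#' @rdname pr_curve
#' @export
aupr <- function(scores, labels) {
  attr(pr_curve(scores, labels), "aupr")
}

#' Compare the four estimators by selection-frequency AUPR
#'
#' Runs lasso, group lasso, SGL and WSGL over a lambda grid on a
#' simulated dataset, scores loci by [selection_frequency()], and
#' evaluates each score vector against the known causal labels with
#' [pr_curve()].
#'
#' @param dataset A [simulate_gwas()] result (or any list with
#'   `genotype`, `phenotype`, `groups`, `truth`).
#' @param alpha Mixing ratio for SGL/WSGL. Default 0.95.
#' @param lambda_grid Lambda values to evaluate.
#'   Default `seq(0.01, 0.1, by = 0.01)`.
#' @param methods Which estimators to run; any of `"lasso"`,
#'   `"group_lasso"`, `"sgl"`, `"wsgl"`.
#' @param n_repeats,subsample_fraction Subsampling protocol passed to
#'   [selection_frequency()].
#' @param standardize Passed to the underlying fits. Defaults to `FALSE`
#'   (centered, unscaled dosages) for method comparison: on the dosage
#'   scale the MAF weights equalize the per-allele selection threshold
#'   across allele frequencies, which is the regime the weighted
#'   estimator targets; scaling every column to unit variance would
#'   cancel the frequency penalty the weights compensate for.
#' @param seed Integer seed (shared across methods so they see the same
#'   subsamples).
#' @return A tibble with one row per method x lambda: `method`, `lambda`,
#'   `aupr`, `n_selected` (mean support size over subsamples is not
#'   tracked; `n_selected` counts loci with nonzero frequency).
#' @export
compare_methods <- function(dataset, alpha = 0.95,
                            lambda_grid = seq(0.01, 0.1, by = 0.01),
                            methods = c("lasso", "group_lasso", "sgl",
                                        "wsgl"),
                            n_repeats = 100L, subsample_fraction = 0.5,
                            standardize = FALSE, seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  X <- as_design_matrix(dataset$genotype)
  y <- dataset$phenotype
  groups <- dataset$groups
  labels <- as.integer(colnames(X) %in% dataset$truth$locus_id)
  w_maf <- maf_weights(compute_maf(X))

  settings <- list(
    lasso = list(alpha = 1, weights = 1),
    group_lasso = list(alpha = 0, weights = 1),
    sgl = list(alpha = alpha, weights = 1),
    wsgl = list(alpha = alpha, weights = w_maf)
  )

  purrr::map_dfr(methods, function(mth) {
    st <- settings[[mth]]
    purrr::map_dfr(lambda_grid, function(lam) {
      sf <- selection_frequency(
        X, y, groups, lambda = lam, alpha = st$alpha, weights = st$weights,
        n_repeats = n_repeats, subsample_fraction = subsample_fraction,
        standardize = standardize, seed = seed)
      tibble::tibble(
        method = mth, lambda = lam,
        aupr = aupr(sf$freq, labels),
        n_selected = sum(sf$freq > 0))
    })
  })
}
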