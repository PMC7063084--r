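#' Minor allele frequency of dosage columns
#'
#' The alternate-allele frequency of a 0/1/2 dosage vector is
#' \eqn{f = \sum d / (2 n_{\mathrm{obs}})} over non-missing entries; the
#' minor allele frequency is the folded value \eqn{\min(f, 1-f)}, so the
#' result is invariant to swapping allele labels (d -> 2-d).
#'
#' @param x A dosage vector with entries in \{0, 1, 2\} (possibly `NA`) —
#'   fractional values in `[0, 2]` from mean imputation are also accepted —
#'   or a dosage matrix, in which case one MAF per column is returned.
#' @return MAF value(s) in `[0, 0.5]`.
#' @examples
#' compute_maf(c(0, 1, 2, 2)) # f = 5/8, folded to 0.375
#' @export
compute_maf <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    return(stats::setNames(apply(x, 2L, compute_maf), colnames(x)))
  }
  obs <- x[!is.na(x)]
  if (length(obs) == 0L) stop("all-missing dosage column", call. = FALSE)
  if (any(obs < 0 | obs > 2)) {
    stop("dosages must lie in [0, 2] or be missing", call. = FALSE)
  }
  f <- sum(obs) / (2 * length(obs))
  min(f, 1 - f)
}

#' MAF-derived penalty weights
#'
#' The per-locus l1 penalty weight is the expected heterozygosity
#' \eqn{\omega = 2\,\mathrm{MAF}(1-\mathrm{MAF})}, strictly increasing in
#' MAF on (0, 0.5], so low-frequency variants receive a smaller penalty
#' and a better chance of staying in the model.
#'
#' @param maf Vector of minor allele frequencies in (0, 0.5]. Monomorphic
#'   loci (MAF 0) must be removed by QC first.
#' @return Weights \eqn{\omega} in (0, 0.5].
#' @examples
#' maf_weights(c(0.01, 0.5)) # 0.0198, 0.5
#' @export
maf_weights <- function(maf) {
  maf <- as.numeric(maf)
  if (any(!is.finite(maf))) stop("MAF must be finite", call. = FALSE)
  if (any(maf <= 0)) {
    stop("MAF of 0 (monomorphic locus): run QC to remove such loci before ",
         "computing weights", call. = FALSE)
  }
  if (any(maf > 0.5)) {
    stop("MAF above 0.5: fold allele frequencies first (see compute_maf())",
         call. = FALSE)
  }
  2 * maf * (1 - maf)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit p-value of observed
#' genotype counts against the Hardy-Weinberg expectations
#' \eqn{(np^2, 2npq, nq^2)}, with the allele frequency estimated from the
#' sample. No continuity correction is applied. Monomorphic counts return
#' p = 1 by convention (no test possible).
#'
#' @param n_ref Count of reference homozygotes (dosage 0).
#' @param n_het Count of heterozygotes (dosage 1).
#' @param n_alt Count of alternate homozygotes (dosage 2).
#' @return p-value in `[0, 1]`.
#' @examples
#' hwe_pvalue(25, 50, 25) # exact HWE proportions: p = 1
#' hwe_pvalue(50, 0, 50)  # total heterozygote deficit: p << 1e-4
#' @export
hwe_pvalue <- function(n_ref, n_het, n_alt) {
  counts <- c(n_ref, n_het, n_alt)
  if (any(counts < 0) || any(counts != round(counts)) || sum(counts) == 0) {
    stop("genotype counts must be nonnegative integers with positive total",
         call. = FALSE)
  }
  n <- sum(counts)
  q <- (2 * n_alt + n_het) / (2 * n)
  if (q == 0 || q == 1) return(1)
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Genotype quality control
#'
#' Removes loci failing any of the standard GWAS filters: minor allele
#' frequency below `maf_min`, missing rate above `miss_max`, or
#' Hardy-Weinberg equilibrium p-value below `hwe_p`. A locus failing
#' several filters is attributed to the first in the order
#' MAF, missingness, HWE. Remaining missing entries are mean-imputed per
#' column, so the returned matrix is ready for [fit_wsgl()].
#'
#' @param X Raw dosage matrix (entries 0/1/2 or `NA`), loci in columns.
#' @param maf_min MAF threshold; loci with MAF `< maf_min` are removed.
#'   Default 0.01.
#' @param miss_max Missing-rate threshold; loci with missing rate
#'   `> miss_max` are removed. Default 0.05.
#' @param hwe_p HWE p-value threshold; loci with p `< hwe_p` are removed.
#'   Default 1e-4.
#' @return A list with `genotype` (the filtered, imputed matrix) and
#'   `report`, a `qc_report` tibble with the input/kept/removed counts and
#'   the kept locus ids.
#' @examples
#' X <- cbind(a = c(0, 1, 2, 1), b = c(0, 0, 0, 0))
#' apply_qc(X)$report
#' @export
apply_qc <- function(X, maf_min = 0.01, miss_max = 0.05, hwe_p = 1e-4) {
  X <- as_design_matrix(X)
  vals <- X[!is.na(X)]
  if (any(vals < 0 | vals > 2)) {
    stop("`X` must hold dosages in [0, 2] (or NA) for QC", call. = FALSE)
  }
  p <- ncol(X)
  maf <- apply(X, 2L, compute_maf)
  miss <- colMeans(is.na(X))
  # HWE uses hard genotype calls only; fractional (imputed) entries are
  # ignored, which also makes QC idempotent on its own imputed output
  hwe <- apply(X, 2L, function(col) {
    obs <- col[!is.na(col) & col %in% c(0, 1, 2)]
    if (length(obs) == 0L) return(1)
    hwe_pvalue(sum(obs == 0), sum(obs == 1), sum(obs == 2))
  })

  fail_maf <- maf < maf_min
  fail_miss <- !fail_maf & miss > miss_max
  fail_hwe <- !fail_maf & !fail_miss & hwe < hwe_p
  keep <- !(fail_maf | fail_miss | fail_hwe)
  if (!any(keep)) stop("QC removed every locus", call. = FALSE)

  Xk <- X[, keep, drop = FALSE]
  for (j in seq_len(ncol(Xk))) {
    na <- is.na(Xk[, j])
    if (any(na)) Xk[na, j] <- mean(Xk[, j], na.rm = TRUE)
  }

  report <- structure(tibble::tibble(
    n_input_loci = p,
    n_removed_maf = sum(fail_maf),
    n_removed_missing = sum(fail_miss),
    n_removed_hwe = sum(fail_hwe),
    n_kept = sum(keep),
    kept_locus_ids = list(colnames(X)[keep])
  ), class = c("qc_report", "tbl_df", "tbl", "data.frame"))

  list(genotype = Xk, report = report)
}
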