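#' Read a genotype matrix from VCF or TSV
#'
#' TSV: a rectangular table whose first column holds sample ids and whose
#' remaining columns are per-locus dosages (header = locus ids). VCF:
#' diploid GT fields are mapped to alternate-allele dosage (0/0 -> 0,
#' 0/1 or 1/0 -> 1, 1/1 -> 2, ./. -> missing); multi-allelic records are
#' skipped with a message, and the skip count is returned as an
#' attribute. With `fold = TRUE` dosage columns are recoded so the counted
#' allele is the panel-wide minor allele (d -> 2-d where the alternate
#' allele frequency exceeds 0.5), matching the MAF-based weight semantics.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param fold Recode to minor-allele dosages. Default `TRUE`.
#' @return Numeric dosage matrix with sample row names and locus column
#'   names; attribute `n_skipped` counts skipped multi-allelic records.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           fold = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else "tsv"
  }
  X <- if (format == "vcf") read_genotypes_vcf(path) else
    read_genotypes_tsv(path)
  if (nrow(X) == 0L) stop("no samples in ", path, call. = FALSE)
  if (fold) {
    af <- colSums(X, na.rm = TRUE) /
      (2 * colSums(!is.na(X)))
    flip <- which(af > 0.5)
    if (length(flip)) X[, flip] <- 2 - X[, flip]
  }
  X
}

read_genotypes_tsv <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tb) < 2L) {
    stop("genotype TSV needs a sample-id column plus >= 1 locus", call. = FALSE)
  }
  X <- as.matrix(tb[, -1L])
  if (!is.numeric(X)) stop("non-numeric dosage entries in ", path, call. = FALSE)
  rownames(X) <- as.character(tb[[1L]])
  X
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(vcf)
  multi <- grepl(",", alt)
  n_skipped <- sum(multi)
  if (n_skipped > 0L) {
    message("skipped ", n_skipped, " multi-allelic record(s)")
    vcf <- vcf[!multi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || nrow(gt) == 0L) {
    stop("no usable biallelic records in ", path, call. = FALSE)
  }
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids) || anyDuplicated(ids)) {
    fix <- vcfR::getFIX(vcf)
    ids <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  }
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    a <- strsplit(g, "[/|]")[[1]]
    if (length(a) != 2L || any(a == ".")) return(NA_real_)
    sum(a == "1")
  })
  X <- t(dose)
  colnames(X) <- ids
  structure(X, n_skipped = n_skipped)
}

#' Write / read package tables as TSV
#'
#' Plain-TSV serializers for the package's tabular artifacts: genotype
#' matrices (first column `sample_id`), phenotypes (`sample_id`, `value`),
#' group maps (`locus_id`, `group_id`) and selection frequencies. Each
#' writer round-trips through its reader.
#'
#' @param X,path,y,groups,freqs Objects/paths as named.
#' @name wsgl_tsv
#' @return Writers return `path` invisibly; readers the parsed object.
#' @export
write_genotypes <- function(X, path) {
  X <- as_design_matrix(X)
  tb <- tibble::as_tibble(X)
  tb <- tibble::add_column(
    tb, sample_id = rownames(X) %||% paste0("sample_", seq_len(nrow(X))),
    .before = 1L)
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

#' @rdname wsgl_tsv
#' @export
read_phenotype <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tb) < 2L) stop("phenotype TSV needs sample_id + value columns",
                          call. = FALSE)
  stats::setNames(as.numeric(tb[[2L]]), as.character(tb[[1L]]))
}

#' @rdname wsgl_tsv
#' @export
write_phenotype <- function(y, path) {
  readr::write_tsv(tibble::tibble(
    sample_id = names(y) %||% paste0("sample_", seq_along(y)),
    value = as.numeric(y)), path, progress = FALSE)
  invisible(path)
}

#' @rdname wsgl_tsv
#' @export
read_groups <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tb) < 2L) stop("group map TSV needs locus_id + group_id columns",
                          call. = FALSE)
  tibble::tibble(locus_id = as.character(tb[[1L]]),
                 group_id = as.character(tb[[2L]]))
}

#' @rdname wsgl_tsv
#' @export
write_groups <- function(groups, path) {
  readr::write_tsv(groups, path, progress = FALSE)
  invisible(path)
}

#' @rdname wsgl_tsv
#' @export
write_selection_frequencies <- function(freqs, path) {
  readr::write_tsv(freqs[, c("locus_id", "freq")], path, progress = FALSE)
  invisible(path)
}

#' Write a fitted model as a coefficient TSV
#'
#' One row per locus: `locus_id`, `group_id`, `maf` (when available),
#' `omega`, `beta_standardized`, `beta_original`.
#'
#' @param fit A `wsgl_fit`.
#' @param path Output file.
#' @param maf Optional per-locus MAF vector to include.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path, maf = NULL) {
  stopifnot(inherits(fit, "wsgl_fit"))
  tb <- tidy(fit)
  if (!is.null(maf)) tb$maf <- as.numeric(maf)[match(tb$locus_id, names(maf))]
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

#' Align genotype rows with a phenotype by sample id
#'
#' Joins strictly on sample identifier (order-independent) and errors on
#' any sample present on one side only.
#'
#' @param X Genotype matrix with sample row names.
#' @param y Named phenotype vector.
#' @return List with aligned `X` and `y`.
#' @export
align_samples <- function(X, y) {
  if (is.null(rownames(X)) || is.null(names(y))) {
    stop("both genotype rows and phenotype entries need sample ids",
         call. = FALSE)
  }
  common <- intersect(rownames(X), names(y))
  missing_x <- setdiff(names(y), rownames(X))
  missing_y <- setdiff(rownames(X), names(y))
  if (length(missing_x) || length(missing_y)) {
    stop("sample ids do not align: ",
         length(missing_y), " genotype-only, ",
         length(missing_x), " phenotype-only (e.g. ",
         paste(head(c(missing_y, missing_x), 3L), collapse = ", "), ")",
         call. = FALSE)
  }
  list(X = X[common, , drop = FALSE], y = y[common])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
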