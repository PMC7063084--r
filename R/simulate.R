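#' Simulation design for a synthetic GWAS panel
#'
#' Bundles the parameters of the synthetic genotype/phenotype generator.
#' The defaults mirror a single-chromosome gene-grouped panel: 200 samples,
#' 1,993 loci partitioned into 200 gene groups, 20 causal loci concentrated
#' in 5 groups with half of them low-frequency (MAF < 0.05), per-allele
#' effect sizes drawn from N(0, `effect_size`^2) and standard-normal
#' phenotype noise.
#'
#' @param n_samples Number of samples. Default 200.
#' @param n_loci Total number of loci. Default 1993.
#' @param n_groups Number of groups (genes); loci are partitioned into
#'   nonempty groups of random sizes. Default 200.
#' @param maf_range Range of the log-uniform MAF distribution.
#'   Default `c(0.01, 0.5)`.
#' @param low_freq_mass Optional extra probability mass below MAF 0.05:
#'   with this probability a locus MAF is drawn log-uniformly from
#'   `[maf_range[1], 0.05]` instead of the full range. `NULL` (default)
#'   uses the plain log-uniform spectrum.
#' @param n_causal Number of causal loci. Default 20.
#' @param n_causal_groups Number of groups holding all causal loci.
#'   Default 5.
#' @param rare_causal_frac Fraction of causal loci required to be
#'   low-frequency (MAF < 0.05). Default 0.5.
#' @param effect_size Scale of the causal effects. Default 1.
#' @param effect_dist `"normal"` draws effects from N(0, `effect_size`^2);
#'   `"fixed"` uses magnitude `effect_size` with random sign.
#' @param effect_scale `"allelic"` (default) places effects on the dosage
#'   (per-allele) scale, so rare variants carry weaker standardized
#'   signal — the regime the MAF-adaptive weights address;
#'   `"standardized"` divides each effect by the locus dosage standard
#'   deviation so every causal locus has equal standardized effect.
#' @param noise_sd Phenotype noise standard deviation. Default 1.
#' @param seed Integer seed for reproducibility.
#' @return A `sim_design` list.
#' @export
sim_design <- function(n_samples = 200L, n_loci = 1993L, n_groups = 200L,
                       maf_range = c(0.01, 0.5), low_freq_mass = NULL,
                       n_causal = 20L, n_causal_groups = 5L,
                       rare_causal_frac = 0.5,
                       effect_size = 1, effect_dist = c("normal", "fixed"),
                       effect_scale = c("allelic", "standardized"),
                       noise_sd = 1, seed = NULL) {
  effect_dist <- match.arg(effect_dist)
  effect_scale <- match.arg(effect_scale)
  if (n_loci < 1L || n_groups < 1L || n_samples < 2L) {
    stop("degenerate design: need >= 1 locus, >= 1 group, >= 2 samples",
         call. = FALSE)
  }
  if (n_groups > n_loci) stop("more groups than loci", call. = FALSE)
  if (n_causal > n_loci) stop("more causal loci than loci", call. = FALSE)
  if (n_causal_groups > n_groups) {
    stop("more causal groups than groups", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  structure(list(
    n_samples = as.integer(n_samples), n_loci = as.integer(n_loci),
    n_groups = as.integer(n_groups), maf_range = maf_range,
    low_freq_mass = low_freq_mass, n_causal = as.integer(n_causal),
    n_causal_groups = as.integer(n_causal_groups),
    rare_causal_frac = rare_causal_frac, effect_size = effect_size,
    effect_dist = effect_dist, effect_scale = effect_scale,
    noise_sd = noise_sd, seed = seed
  ), class = "sim_design")
}

draw_mafs <- function(design) {
  lo <- design$maf_range[1]
  hi <- design$maf_range[2]
  f <- exp(runif(design$n_loci, log(lo), log(hi)))
  if (!is.null(design$low_freq_mass) && design$low_freq_mass > 0) {
    rare <- runif(design$n_loci) < design$low_freq_mass
    f[rare] <- exp(runif(sum(rare), log(lo), log(min(0.05, hi))))
  }
  f
}

#' Simulate a group-structured genotype panel
#'
#' Draws each locus as Binomial(2, f) dosages with per-locus allele
#' frequencies from a log-uniform MAF spectrum (optionally enriched below
#' 0.05), and partitions the loci into contiguous nonempty gene groups of
#' random sizes. Columns that come out monomorphic at the sampled panel
#' size are redrawn so every locus is usable downstream. Loci are
#' independent; within-gene linkage disequilibrium is not modelled.
#'
#' @param design A [sim_design()].
#' @return A list with `genotype` (dosage matrix with sample/locus ids),
#'   `groups` (per-locus group labels) and `maf` (the generating allele
#'   frequencies).
#' @export
simulate_genotypes <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  with_local_seed(design$seed, {
    n <- design$n_samples
    p <- design$n_loci
    m <- design$n_groups
    f <- draw_mafs(design)
    X <- vapply(f, function(fi) rbinom(n, 2L, fi), numeric(n))
    for (j in seq_len(p)) {
      tries <- 0L
      while (var(X[, j]) == 0 && tries < 100L) {
        X[, j] <- rbinom(n, 2L, f[j])
        tries <- tries + 1L
      }
      if (var(X[, j]) == 0) X[sample.int(n, 1L), j] <- 1L
    }
    rownames(X) <- sprintf("sample_%04d", seq_len(n))
    colnames(X) <- sprintf("snp_%05d", seq_len(p))
    sizes <- as.vector(stats::rmultinom(1L, p - m, rep(1 / m, m))) + 1L
    groups <- rep(sprintf("gene_%04d", seq_len(m)), times = sizes)
    list(genotype = X, groups = groups,
         maf = stats::setNames(f, colnames(X)))
  })
}

#' Simulate a phenotype from a genotype panel
#'
#' Draws a sparse causal coefficient vector concentrated in
#' `n_causal_groups` groups — with a quota of low-frequency causal loci —
#' and generates \eqn{y = X\beta + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2)} i.i.d. The returned `truth`
#' records the causal loci, their effects, and the exact noise vector, so
#' `y - X beta` reproduces the stored noise bit for bit.
#'
#' @param genotype Dosage matrix (loci in columns).
#' @param groups Per-locus group assignment.
#' @param design A [sim_design()]; its `seed` is used if `seed` is `NULL`.
#' @param seed Optional seed overriding the design's.
#' @return A list with `phenotype`, `truth` (tibble: locus_id, group,
#'   maf, effect, beta) and `noise`.
#' @export
simulate_phenotype <- function(genotype, groups, design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  X <- as_design_matrix(genotype)
  grp <- as_group_index(groups, X)
  p <- ncol(X)
  if (design$n_causal > p) stop("more causal loci than loci", call. = FALSE)
  seed <- if (is.null(seed)) design$seed else seed

  with_local_seed(seed, {
    maf <- compute_maf(X)
    rare <- maf < 0.05
    n_rare <- min(ceiling(design$rare_causal_frac * design$n_causal),
                  sum(rare))
    n_common <- design$n_causal - n_rare

    # choose causal groups so the rare/common quota is satisfiable
    causal <- NULL
    for (try in 1:200) {
      gsel <- sample.int(grp$m, design$n_causal_groups)
      pool <- which(grp$index %in% gsel)
      if (length(pool) < design$n_causal) next
      pr <- pool[rare[pool]]
      pc <- pool[!rare[pool]]
      if (length(pr) < n_rare || length(pc) < n_common) next
      causal <- c(sample(pr, n_rare), sample(pc, n_common))
      break
    }
    if (is.null(causal)) {
      # fall back: fill the quota as far as the panel allows
      gsel <- sample.int(grp$m, design$n_causal_groups)
      pool <- which(grp$index %in% gsel)
      while (length(pool) < design$n_causal) {
        gsel <- unique(c(gsel, sample.int(grp$m, 1L)))
        pool <- which(grp$index %in% gsel)
      }
      causal <- sample(pool, design$n_causal)
    }
    causal <- sort(causal)

    eff <- switch(design$effect_dist,
      normal = rnorm(design$n_causal, 0, design$effect_size),
      fixed = design$effect_size * sample(c(-1, 1), design$n_causal,
                                          replace = TRUE))
    beta <- numeric(p)
    beta[causal] <- eff
    if (design$effect_scale == "standardized") {
      sds <- apply(X[, causal, drop = FALSE], 2L, function(col) {
        sqrt(mean((col - mean(col))^2))
      })
      beta[causal] <- eff / sds
    }
    noise <- rnorm(nrow(X), 0, design$noise_sd)
    xb <- as.vector(X %*% beta)
    y <- xb + noise
    names(y) <- rownames(X)
    # store the noise as y - Xb so the phenotype identity y = Xb + noise
    # holds bit for bit when the residual is recomputed downstream
    noise <- unname(y - xb)

    truth <- tibble::tibble(
      locus_id = colnames(X)[causal],
      group = grp$labels[grp$index[causal]],
      maf = unname(maf[causal]),
      effect = eff,
      beta = beta[causal]
    )
    list(phenotype = y, truth = truth, noise = noise)
  })
}

#' Simulate a complete synthetic GWAS dataset
#'
#' Convenience wrapper combining [simulate_genotypes()] and
#' [simulate_phenotype()].
#'
#' @param design A [sim_design()].
#' @return A `sim_gwas` list: `genotype`, `phenotype`, `groups`, `maf`,
#'   `truth`, `noise`, and the `design`.
#' @examples
#' sim <- simulate_gwas(sim_design(n_samples = 50, n_loci = 30,
#'                                 n_groups = 6, n_causal = 3,
#'                                 n_causal_groups = 2, seed = 7))
#' sim$truth
#' @export
simulate_gwas <- function(design) {
  geno <- simulate_genotypes(design)
  seed2 <- if (is.null(design$seed)) NULL else design$seed + 1L
  pheno <- simulate_phenotype(geno$genotype, geno$groups, design,
                              seed = seed2)
  structure(list(
    genotype = geno$genotype,
    phenotype = pheno$phenotype,
    groups = geno$groups,
    maf = geno$maf,
    truth = pheno$truth,
    noise = pheno$noise,
    design = design
  ), class = "sim_gwas")
}
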