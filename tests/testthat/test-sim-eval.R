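test_that("genotype simulation matches the requested panel geometry", {
  des <- sim_design(n_samples = 60, n_loci = 1993, n_groups = 200, seed = 2)
  g <- simulate_genotypes(des)
  expect_equal(dim(g$genotype), c(60L, 1993L))
  expect_equal(length(unique(g$groups)), 200L)
  expect_equal(as.vector(table(factor(g$groups, unique(g$groups)))) |> sum(),
               1993L)
  expect_true(all(g$genotype %in% 0:2))
  expect_true(all(apply(g$genotype, 2, var) > 0))

  g2 <- simulate_genotypes(des)
  expect_identical(g$genotype, g2$genotype)
  expect_error(sim_design(n_loci = 0), "degenerate")
})

test_that("empirical allele frequency concentrates at the generating MAF", {
  des <- sim_design(n_samples = 10000, n_loci = 5, n_groups = 1,
                    n_causal = 1, n_causal_groups = 1,
                    maf_range = c(0.3, 0.3), seed = 8)
  g <- simulate_genotypes(des)
  emp <- colMeans(g$genotype) / 2
  expect_true(all(abs(emp - 0.3) < 0.01))
})

test_that("the low-frequency mass option enriches below MAF 0.05", {
  des_plain <- sim_design(n_loci = 2000, n_groups = 10, seed = 3)
  des_rare <- sim_design(n_loci = 2000, n_groups = 10, seed = 3,
                         low_freq_mass = 0.8)
  set.seed(3); f1 <- wsgl:::draw_mafs(des_plain)
  set.seed(3); f2 <- wsgl:::draw_mafs(des_rare)
  expect_gt(mean(f2 < 0.05), mean(f1 < 0.05))
})

test_that("phenotype equals X beta plus the stored noise, exactly", {
  des <- sim_design(n_samples = 80, n_loci = 100, n_groups = 10,
                    n_causal = 20, n_causal_groups = 5, seed = 12)
  sim <- simulate_gwas(des)
  expect_equal(nrow(sim$truth), 20L)
  expect_true(all(sim$truth$beta != 0))
  expect_lte(length(unique(sim$truth$group)), 5L)
  beta <- numeric(ncol(sim$genotype))
  beta[match(sim$truth$locus_id, colnames(sim$genotype))] <- sim$truth$beta
  resid <- sim$phenotype - as.vector(sim$genotype %*% beta)
  expect_identical(unname(resid), sim$noise)

  # noiseless limit
  des0 <- sim_design(n_samples = 40, n_loci = 30, n_groups = 5,
                     n_causal = 3, n_causal_groups = 2, noise_sd = 0,
                     seed = 12)
  sim0 <- simulate_gwas(des0)
  b0 <- numeric(30)
  b0[match(sim0$truth$locus_id, colnames(sim0$genotype))] <- sim0$truth$beta
  expect_equal(unname(sim0$phenotype), as.vector(sim0$genotype %*% b0))

  # null model: pure standard normal noise
  desn <- sim_design(n_samples = 5000, n_loci = 10, n_groups = 2,
                     n_causal = 0, n_causal_groups = 1, seed = 13)
  simn <- simulate_gwas(desn)
  expect_equal(var(simn$phenotype), 1, tolerance = 0.1)
})

test_that("rare-causal quota is honoured", {
  des <- sim_design(n_samples = 150, n_loci = 400, n_groups = 40,
                    n_causal = 20, n_causal_groups = 5,
                    rare_causal_frac = 0.5, low_freq_mass = 0.5, seed = 21)
  sim <- simulate_gwas(des)
  expect_gte(sum(sim$truth$maf < 0.05), 10)
})

test_that("PR curve and AUPR match brute-force enumeration", {
  expect_equal(aupr(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(aupr(c(0.2, 0.9, 0.5), c(1, 1, 1)), 1.0)
  expect_error(aupr(c(1, 2), c(0, 0)), "positive")

  set.seed(31)
  for (case in 1:20) {
    n <- sample(5:50, 1)
    scores <- round(runif(n), sample(1:3, 1))  # force ties sometimes
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0) labels[sample(n, 1)] <- 1
    expect_equal(aupr(scores, labels), oracle_aupr(scores, labels))
  }
})

test_that("PR curve recall is non-decreasing and permutation-invariant", {
  set.seed(32)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.25)
  labels[1] <- 1
  pr <- pr_curve(scores, labels)
  expect_true(all(diff(pr$recall) >= 0))
  expect_gte(attr(pr, "aupr"), 0)
  expect_lte(attr(pr, "aupr"), 1)
  perm <- sample(40)
  expect_equal(aupr(scores[perm], labels[perm]), aupr(scores, labels))
})

test_that("random scores give AUPR near the positive fraction", {
  set.seed(33)
  q <- 0.15
  labels <- rbinom(1000, 1, q)
  a <- mean(replicate(20, aupr(runif(1000), labels)))
  expect_lt(abs(a - mean(labels)), 0.05)
})

test_that("compare_methods produces one row per method and lambda", {
  sim <- simulate_gwas(sim_design(
    n_samples = 60, n_loci = 40, n_groups = 8, n_causal = 4,
    n_causal_groups = 2, seed = 41))
  tb <- compare_methods(sim, lambda_grid = 0.05, methods = "wsgl",
                        n_repeats = 3, seed = 1)
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$method, "wsgl")

  # forcing unit weights makes WSGL and SGL coincide
  tb2 <- compare_methods(sim, lambda_grid = c(0.03, 0.06),
                         methods = c("sgl", "wsgl"), n_repeats = 5,
                         seed = 2)
  tb2w <- dplyr::filter(tb2, method == "wsgl")
  # same protocol with weights overridden to 1 via selection_frequency
  sf <- selection_frequency(sim$genotype, sim$phenotype, sim$groups,
                            lambda = 0.03, alpha = 0.95, weights = 1,
                            standardize = FALSE, n_repeats = 5, seed = 2)
  labels <- as.integer(colnames(sim$genotype) %in% sim$truth$locus_id)
  expect_equal(dplyr::filter(tb2, method == "sgl", lambda == 0.03)$aupr,
               aupr(sf$freq, labels))
})
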