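# wsgl — weighted sparse group lasso for genetic variant selection

`wsgl` fits penalized linear models for group-structured genome-wide
association studies, where loci (SNPs) are organised into genes and a
quantitative trait is modelled as

```
y = X β + ε,    ε ~ N(0, σ²)
```

with `X` an n × p minor-allele dosage matrix. The centrepiece is the
**weighted sparse group lasso**:

```
min_β  (1/2n) ‖y − Σ_l X⁽l⁾β⁽l⁾‖₂²
       + (1−α) λ Σ_l √p_l ‖β⁽l⁾‖₂
       + α λ Σ_j ω_j |β_j|
```

The group ℓ2 term selects a few genes, the ℓ1 term selects loci within
them, and the per-locus weights

```
ω_j = 2·MAF_j·(1 − MAF_j)
```

(the expected heterozygosity) lighten the ℓ1 penalty on low-frequency
variants, so rare causal variants are not swept out before common
variants of equal per-allele effect. Special cases are exact: `α = 1`
with unit weights is the lasso, `α = 0` the group lasso, unit weights
the sparse group lasso (SGL). The solver is block coordinate descent
with group-level screening, written in C++ (RcppArmadillo); fits are
deterministic, convergence is certified against the subgradient (KKT)
optimality conditions, and zero coefficients are exact zeros.

Around the estimator the package provides:

- `apply_qc()` — genotype QC (MAF < 0.01, missing rate > 0.05,
  Hardy–Weinberg χ² p < 1e-4; mean imputation), plus `compute_maf()`,
  `maf_weights()`, `hwe_pvalue()`
- `cv_wsgl()` — k-fold cross-validated λ over a grid (default
  0.01–0.10 by 0.01)
- `selection_frequency()` — stability-selection-style locus scores over
  random half-subsamples
- `simulate_gwas()` — synthetic gene-grouped panels with a realistic
  MAF spectrum, sparse causal architecture and Gaussian noise
- `pr_curve()` / `aupr()` / `compare_methods()` — precision–recall
  evaluation of locus scores under class imbalance
- `read_genotypes()` (VCF or TSV), `assign_groups()` (BED/GFF gene
  intervals), TSV writers, and a command-line interface
  (`inst/cli/wsgl-cli.R` with subcommands `qc`, `fit`, `cv`,
  `simulate`, `evaluate`)

Results are tibbles with `tidy()` / `glance()` methods and `autoplot()`
figures throughout.

## Worked example

```r
library(wsgl)

# a synthetic panel: 200 samples, 500 SNPs in 50 genes, 20 causal SNPs
# (half of them low-frequency) concentrated in 5 genes
sim <- simulate_gwas(sim_design(n_samples = 200, n_loci = 500,
                                n_groups = 50, n_causal = 20,
                                n_causal_groups = 5, seed = 1))

w  <- maf_weights(compute_maf(sim$genotype))
cv <- cv_wsgl(sim$genotype, sim$phenotype, sim$groups, weights = w,
              standardize = FALSE, seed = 1)
glance(cv)
#> # A tibble: 1 × 4
#>   best_lambda cv_error k_folds alpha
#>         <dbl>    <dbl>   <int> <dbl>
#> 1         0.1     1.86       5  0.95

fit <- fit_wsgl(sim$genotype, sim$phenotype, sim$groups,
                lambda = glance(cv)$best_lambda, weights = w,
                standardize = FALSE)
fit
#> <wsgl_fit> weighted sparse group lasso | n = 200, p = 500, 50 groups
#>   lambda = 0.1, alpha = 0.95
#>   nonzero loci: 193 in 35 groups | converged after 24 sweeps

# score loci by selection frequency and evaluate against the truth
sf <- selection_frequency(sim$genotype, sim$phenotype, sim$groups,
                          lambda = glance(cv)$best_lambda, weights = w,
                          standardize = FALSE, n_repeats = 50, seed = 1)
labels <- colnames(sim$genotype) %in% sim$truth$locus_id
aupr(sf$freq, labels)
#> [1] 0.632089
```

The fitted object reports coefficients on both the centered-dosage and
original scales (`tidy(fit)`), the per-sweep objective trace (always
non-increasing) and a convergence flag that is only set once the KKT
residuals pass `tol_kkt`. An AUPR of 0.63 here means the
selection-frequency ranking places causal loci far above the 4%
causal base rate (the AUPR a random ranking would achieve).

`standardize = FALSE` (centered, unscaled dosages) is the recommended
mode for MAF-weighted selection: on the dosage scale the weights make
the ℓ1 selection threshold invariant to allele frequency for a given
per-allele effect. See the methods vignette
(`vignettes/wsgl-methods.Rmd`) for the full argument.

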