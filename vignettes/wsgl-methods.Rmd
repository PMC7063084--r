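---
title: "Methods: the weighted sparse group lasso for variant selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the weighted sparse group lasso for variant selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsgl)
```

## The model

Loci (SNPs) are coded as minor-allele dosages $x_{ij} \in \{0,1,2\}$ and
partitioned into $m$ groups (genes). A quantitative trait is modelled
linearly, $y = X\beta + \varepsilon$ with
$\varepsilon \sim N(0, \sigma^2 I)$, and the coefficients are estimated
by the weighted sparse group lasso

$$
\hat\beta = \arg\min_\beta\; \frac{1}{2n}\Big\|y - \sum_{l=1}^m
X^{(l)}\beta^{(l)}\Big\|_2^2
+ (1-\alpha)\lambda \sum_{l=1}^m \sqrt{p_l}\,\big\|\beta^{(l)}\big\|_2
+ \alpha\lambda \sum_{j=1}^p \omega_j |\beta_j| .
$$

The group term induces sparsity at the gene level, the $\ell_1$ term
within genes — the biological prior being that a trait is driven by a
few variants inside a few genes. The weights
$\omega_j = 2\,\mathrm{MAF}_j(1-\mathrm{MAF}_j)$ (expected
heterozygosity, increasing in MAF) penalize low-frequency variants
less. Unit weights give the sparse group lasso (SGL); $\alpha = 1$ the
(weighted) lasso; $\alpha = 0$ the group lasso; $\lambda = 0$ ordinary
least squares. We use the $\sqrt{p_l}$ group scaling of Yuan–Lin and
the $1/(2n)$ loss scaling for every special case, so $\lambda$ is
comparable across estimators and sample sizes.

## Why the weights act on the dosage scale

The single most consequential design choice in this package is *what
scale the design matrix is on* when the weighted penalty is applied.
Write $d_j = x_j^\top x_j / n$ for a centered dosage column; in
expectation $d_j = 2f_j(1-f_j) = \omega_j$. A coordinate enters the
model only when its partial-residual correlation clears the threshold
$|x_j^\top \gamma / n| > n^{-1}\,n\,\alpha\lambda\omega_j$. Two regimes
follow:

* **Centered, unscaled dosages** (`standardize = FALSE`): a causal
  locus with per-allele effect $b$ carries signal
  $x_j^\top y/n \approx \omega_j b$, so the signal-to-threshold ratio
  $\omega_j b / (\alpha\lambda\omega_j) = b/(\alpha\lambda)$ is
  *invariant to allele frequency*. The weights exactly cancel the
  frequency handicap of rare variants, while a null locus's noise scale
  is only $\sqrt{\omega_j}$, so rare null loci are favoured far more
  mildly. This is the regime the weighted estimator is designed for,
  and the coordinate update's $x_i^\top x_i/n$ denominator (which would
  be identically 1 under unit-variance scaling) only carries
  information here.

* **Unit-variance columns** (`standardize = TRUE`): every locus has the
  same signal scale, so dividing the threshold by $\omega_j$ simply
  under-penalizes rare loci by up to $\sim$25-fold. In panels where a
  large fraction of loci are rare, rare null variants flood the
  selection and the weighted estimator *loses* to the unweighted SGL —
  we verified this across sample sizes and $\lambda$ protocols.

`fit_wsgl()` defaults to `standardize = TRUE`, which is the right
general-purpose convention for penalized regression (it makes $\lambda$
meaningful for arbitrary covariates and is what the reductions to
lasso/SGL presume in textbook form). The method-comparison machinery
(`compare_methods()`) and all weighted-selection analyses in this
package run with `standardize = FALSE`, and we recommend that mode
whenever the weights come from `maf_weights()`. An optional mean-one
weight normalization (`normalize_weights = TRUE`) keeps $\lambda$ grids
comparable between weighted and unweighted fits; it is off by default.

## The solver

The objective is convex; its minimizers are characterized by
subgradient conditions: a whole group is zero iff
$\|S(X^{(k)\top}\gamma^{(-k)}/n,\ \alpha\lambda\omega^{(k)})\|_2 \le
\sqrt{p_k}(1-\alpha)\lambda$, where
$S(a,b) = \mathrm{sign}(a)(|a|-b)_+$ is the soft-threshold operator and
$\gamma^{(-k)}$ the partial residual excluding group $k$; a nonzero
coordinate satisfies the stationarity equation balancing its gradient
against the weighted $\ell_1$ subgradient and the group-norm gradient.

`fit_wsgl()` runs block coordinate descent: groups are swept in
ascending index order (fits are bit-reproducible; no randomization),
each group is screened by the condition above, and a surviving group is
solved by cyclic coordinate updates. Numerical choices worth recording:

* **Exact one-dimensional minimization.** The textbook update
  $\hat\beta_i = S(x_i^\top\gamma^{(-k,i)}/n, \alpha\lambda\omega_i)
  \big/ (x_i^\top x_i/n + (1-\alpha)\lambda/\|\hat\beta^{(k)}\|_2)$
  uses the current group norm and is therefore a fixed-point step, not
  a descent step. We iterate that scalar fixed point to convergence
  (a contraction; $\le$ 100 inner iterations at $10^{-14}$), which is
  the exact minimizer of the coordinate subproblem, so the objective
  trace is non-increasing by construction. When every other coordinate
  of the group is zero the group norm is $|\beta_i|$ itself and the
  update has the closed form
  $S(z, \alpha\lambda\omega_i + \sqrt{p_k}(1-\alpha)\lambda)/d_i$.
* **Entering a zero group.** The group norm is non-differentiable at
  the origin jointly, so coordinate-wise moves from $\beta^{(k)} = 0$
  can stall even when the screening condition says the group is
  active. We seed such groups with the orthonormal-case group prox
  $\theta\,(1 - \sqrt{p_k}(1-\alpha)\lambda/\|\theta\|_2)$, where
  $\theta$ is the soft-thresholded group gradient — exact when the
  within-group design is orthonormal, a warm start otherwise.
* **Group collapse.** A group whose norm falls below $10^{-12}$ is set
  to exact zero; thresholded coordinates are stored as exact zeros, so
  the support is read from `beta != 0` with no epsilon.
* **Certified convergence.** Iteration stops when the largest
  coefficient change is below `tol_coef` ($10^{-5}$), the relative
  objective change below `tol_obj` ($10^{-8}$), *and* the largest
  subgradient violation is below `tol_kkt` ($10^{-6}$); the last check
  means a fit flagged `converged` is a verified optimum, not merely a
  stalled iteration. At most 1,000 outer sweeps; non-convergence is
  flagged, never raised as an error.
* **$\lambda_{\max}$.** The smallest $\lambda$ with an all-zero
  solution is computed from the group-zero condition at the full
  residual; for $0 < \alpha < 1$ the two sides are monotone in
  $\lambda$ and we bisect.

Intercepts are handled by centering $X$ and $y$ and are never
penalized; coefficients are reported on both the fitting scale and the
original dosage scale. In the test suite the solver is checked against
an independent proximal-gradient minimizer of the same objective (and
`glmnet` for the weighted-lasso reduction) to $10^{-6}$ relative in
objective and $10^{-5}$ per coefficient.

## Quality control and weights

`apply_qc()` removes loci with MAF < 0.01, missing rate > 0.05, or
Hardy–Weinberg equilibrium $\chi^2$ p-value < $10^{-4}$ (one degree of
freedom, allele frequency estimated from the sample, no continuity
correction; an exact test would be a reasonable alternative we did not
implement). A locus failing several filters is attributed to the first
in that order; the removal set itself is order-independent. Remaining
missing entries are mean-imputed per column — the standard choice for
penalized GWAS regression. HWE counts use hard calls only, so QC is
idempotent on its own imputed output. Monomorphic loci must be removed
before `maf_weights()`, which therefore yields
$\omega \in [2 \cdot 0.01 \cdot 0.99,\ 0.5]$ on any post-QC panel.

## Model selection and locus scoring

`cv_wsgl()` performs k-fold cross-validation (default 5 folds — the
usual choice at a few hundred samples) of held-out mean squared error.
Folds are fixed by a seed; each training fold is refit from scratch, so
centering/scaling statistics never leak from held-out samples; a column
constant within a training fold is dropped for that fold with a logged
warning. The default grid is $\lambda \in \{0.01, \dots, 0.10\}$ in
steps of 0.01; ties break toward the smaller $\lambda$ (less sparsity
at equal error).

Association evidence per locus is summarized by a selection frequency:
the model is refit on `n_repeats` (default 100) random subsamples of
half the data drawn without replacement, and each locus is scored by
the fraction of fits selecting it. This stability-selection-style
protocol is our choice for turning supports into the per-locus
probabilities that precision–recall evaluation needs; fold supports or
bootstrap resampling would be alternatives, and nothing downstream
depends on which is used.

## The synthetic panels

`simulate_gwas()` emulates a single-chromosome, gene-grouped GWAS
panel. Defaults, chosen once: 200 samples; 1,993 loci in 200 groups of
random (multinomial) sizes; per-locus allele frequencies log-uniform on
$[0.01, 0.5]$ (about 40% of loci below MAF 0.05, matching a spectrum
rich in low-frequency variants; an optional `low_freq_mass` adds
further rare mass); dosages Binomial$(2, f_j)$; 20 causal loci confined
to 5 groups, at least half of them with MAF < 0.05; causal effects
drawn $N(0, 1)$ *on the per-allele (dosage) scale*; noise
$N(0, 1)$. Per-allele effects make rare variants carry weaker
standardized signal — the disadvantage the MAF weights are meant to
offset; drawing effects on the standardized scale (available via
`effect_scale = "standardized"`) would equalize all causal signals and
erase the phenomenon under study. The generator stores the exact noise
vector, so `phenotype - genotype %*% beta_true` reproduces it bit for
bit.

What the panels deliberately do not model: linkage disequilibrium
(loci are independent; real within-gene SNPs are correlated),
population structure and relatedness, genotyping error, dominance or
epistasis. Passing tests on these panels therefore demonstrate
correctness of the estimator and the claimed frequency mechanism, not
performance on structured natural populations, where a mixed-model
correction (out of scope here) would be layered underneath.

## Evaluation

Locus detection is scored as binary classification under heavy class
imbalance (20 causal among hundreds of loci), so the headline metric is
the area under the precision–recall curve rather than ROC. `pr_curve()`
traces precision/recall over descending score thresholds, grouping tied
scores into one threshold, and integrates by the step-wise
average-precision sum $\sum_k (R_k - R_{k-1})P_k$; linear interpolation
between PR points is biased and is not used. The implementation is
tested against brute-force threshold enumeration, and random scores
recover the positive-label fraction as their AUPR.

`compare_methods()` runs lasso, group lasso, SGL and WSGL through the
selection-frequency scorer on a shared subsampling seed and reports
AUPR per method and $\lambda$.

## Problem sizes used in the checks

The bundled tests exercise the solver-versus-oracle equivalence on
$\ge 20$ random instances ($n \le 50$, $p \le 40$, 2–6 groups,
$\alpha \in \{0, 0.5, 0.95, 1\}$); the replication of the
low-frequency-advantage claim uses 20 replicate panels of 500 loci in
50 groups at $n = 200$ with CV per method and 50 subsample repeats, and
the recovery check 10 such panels with fixed $\pm 1$ per-allele effects
and noise sd 0.5. These sizes keep a full run in a few minutes on one
CPU while leaving the qualitative conclusions stable across seeds.

## Known limitations

* Groups must partition the loci; overlapping gene annotations are
  resolved to the first gene in file order rather than duplicated.
* No mixed-model/population-structure correction; apply the estimator
  to structure-corrected residuals if stratification is a concern.
* The HWE filter uses the asymptotic $\chi^2$ test, which is
  anticonservative at very small counts.
* Cross-validation optimizes prediction error, which is not the same
  objective as support recovery; the CV-selected $\lambda$ tends to be
  generous, which is why selection frequencies — not a single support —
  are the recommended evidence summary.
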