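---
title: "Polygenic risk scores in prsforge: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic risk scores in prsforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A polygenic risk score (PRS) condenses the genotypes of one individual —
allele counts $G_{ij} \in \{0,1,2\}$ over $p$ SNPs — into a single number
predicting disease liability. `prsforge` implements and compares the two
families of PRS construction that dominate practice:

* **C+T (clumping + thresholding)**: per-SNP GWAS effects $\hat\beta_j$
  with P-values $p_j$, pruned for linkage disequilibrium (LD) and filtered
  at a P-value threshold, then summed as
  $PRS_i = \sum_{j \in S_{clump},\, p_j < p_T} \hat\beta_j G_{ij}$.
* **PLR / PLR3 (penalized logistic regression)**: all SNPs fitted jointly
  by elastic-net penalized regression, with the penalty chosen
  automatically by Cross-Model Selection and Averaging (CMSA). PLR3 is the
  same fit on a tripled design capturing additive, recessive and dominant
  codings per SNP.

Because individual-level biobank genotypes cannot be shipped with a
package, every claim here is exercised on synthetic data from the
package's own genotype and phenotype simulators, at sizes a desk machine
handles in minutes. What that does and does not establish about real data
is discussed at the end.

# The penalized model

For a binary phenotype $y \in \{0,1\}^n$ with covariates folded into $x$,
the solver minimizes

$$ L(\lambda, \alpha) \;=\; \frac{1}{n}\sum_{i=1}^n
   -\bigl[y_i \log z_i + (1-y_i)\log(1-z_i)\bigr]
   \;+\; \lambda\Bigl((1-\alpha)\tfrac12\lVert\beta\rVert_2^2
   + \alpha\lVert\beta\rVert_1\Bigr), $$

with $z_i = 1/(1+e^{-(\beta_0 + x_i^T\beta)})$. The **mean** (1/n) loss is
a deliberate convention — it makes $\lambda$ comparable across sample
sizes; an unnormalized-sum parameterization corresponds to
$\lambda_{sum} = n\lambda$. $\alpha$ interpolates between ridge
($\alpha\to 0$, dense shrinkage, gBLUP-like) and lasso ($\alpha = 1$,
sparse selection); the embedded grid is $\alpha \in \{1, 0.5, 0.05,
0.001\}$. The linear (squared-error) family is available for quantitative
traits.

## The path solver

`fit_path()` runs cyclic coordinate descent over a log-spaced sequence of
`n_lambda = 200` penalties from $\lambda_{max}$ (the KKT entry point at
which every penalized coefficient is zero) down to
`lambda_min_ratio` $\cdot\,\lambda_{max}$ (1e-4 when $n > p$, 1e-2
otherwise), warm-starting each solution from the previous one. Logistic
fits use an outer IRLS quadratic approximation around the current linear
predictor with weighted soft-threshold updates inside.

Three guards make this exact rather than heuristic:

* **Sequential strong rules** screen out predictors whose null-residual
  correlation is too small to become active at the next $\lambda$; after
  convergence on the screened set a **full KKT sweep** over all $p$
  predictors re-admits any violator and re-solves, so screening can never
  change a solution (verified to 1e-8 in the tests).
* Convergence is declared when the largest coefficient update on the
  standardized scale falls below `tol = 1e-7`.
* Solutions are checked in the test suite against an independent
  proximal-gradient (FISTA) minimizer of the same objective, and against
  glmnet where the two parameterizations coincide (lasso both families,
  logistic elastic net; glmnet's gaussian elastic-net path standardizes
  the response internally and thus solves a differently-scaled L2 term).

Two standard runtime controls are exposed: `patience` (early stopping:
the path is abandoned once the validation loss has not improved for 10
consecutive $\lambda$ steps) and `dfmax` (the path is abandoned once a
solution exceeds a requested number of nonzero coefficients, as in
glmnet; already-computed solutions are kept). Neither affects any
returned solution — they only truncate where the path stops.

## CMSA

`cmsa_fit()` removes both hyper-parameters from the user's hands. The
training rows are split into $K = 10$ stratified folds. For each fold and
each $\alpha$, a path is fitted on the other $K-1$ folds with the held-out
fold as validation set (early-stopped as above). Each fold's winner is the
$(\alpha, \lambda)$ minimizing validation deviance — deviance rather than
AUC because it is smooth, defined for both families, and strictly proper;
ties resolve toward larger $\lambda$, then larger $\alpha$ (the sparser
model). The $K$ winning models are then **averaged coefficient-wise on the
raw allele-count scale, structural zeros included**: a predictor chosen by
3 of 10 folds keeps 3/10 of its weight. No refit happens. Averaging
coefficients and averaging fold predictions are the same linear operation,
so AUC — which only ranks the linear predictor — is indifferent between
the two readings.

One behavioral consequence worth knowing: with the near-ridge grid member
$\alpha = 0.001$ a fold winner is dense by construction (ridge never
zeroes coefficients), so `n_predictors` is only a sparsity measure when
the data actually favor the lasso-like grid members. On null data the
lasso-only grid stays near-empty; the full grid need not.

## PLR3: the triple encoding

`triple_encode()` maps each SNP to three columns — the allele count, a
recessive indicator $1\{G = 2\}$ and a dominant indicator $1\{G \ge 1\}$
(so count 1 maps to $(1, 0, 1)$ and count 2 to $(2, 1, 1)$) — giving
exactly $3p$ predictors. The penalized fit then allocates weight between
codings per SNP, which captures departures from additivity at the price
of a threefold design.

# The C+T baseline

`gwas()` fits one regression per SNP (Newton–Raphson for the logistic
family to a gradient norm of 1e-8; on (quasi-)separated SNPs the Wald
statistic degenerates, so the P-value falls back to the score test under
the covariate-only null). `clump()` implements greedy LD clumping:
repeatedly take the unassigned SNP with the smallest P-value (ties:
smaller position, then smaller column index — determinism matters for
reproducibility), prune every unassigned SNP on the same chromosome
within ±500 kb whose squared correlation with it exceeds `r2_threshold`
(default 0.2; 0.05 and 0.8 are the conventional alternatives).
`ct_variants()` evaluates three scores:

* `C+T-all` — every clumped SNP ($p_T = 1$);
* `C+T-stringent` — genome-wide significance, $p_T = 5\times10^{-8}$;
* `C+T-max` — the AUC argmax over a grid of 102 thresholds log-spaced
  between 1 and $10^{-100}$ (ties toward the larger threshold).

Two deliberate protocol quirks are preserved because the comparison they
serve defines them: the LD reference for clumping defaults to the *test*
rows, and `C+T-max` picks its threshold on the *test* AUC. Both make C+T
look better than an honestly-tuned version of itself; `C+T-max` is
flagged `optimistic` in the output, and both knobs are parameters
(`ld_rows`, a training-set grid) for users who want leak-free variants.
PRS weights multiply raw allele counts, not standardized ones — that is
the definition of the score.

# The simulators

## Genotypes

`simulate_genotypes()` draws each individual as the sum of two
independent haplotypes. A haplotype within an LD block follows a Gaussian
copula: a latent AR(1) process with parameter `within_block_rho`,
thresholded at each SNP's MAF quantile. Marginals are therefore exactly
Binomial(2, maf) — Hardy-Weinberg by construction — while adjacent SNPs
within a block are correlated and blocks are independent. MAFs are
uniform on `maf_range` (default 0.05–0.5). Variants are assigned evenly
to chromosomes with positions every 5 kb, so a 500 kb clumping window
spans ±100 SNPs. This emulates the block-correlation structure that makes
clumping and the grouping behavior of the elastic net non-trivial; it
does **not** emulate realistic human LD decay, population structure,
relatedness, or imputation noise.

## Phenotypes

`simulate_phenotype()` implements the liability threshold model. For the
additive (ADD) model, causal effects $w_j$ on standardized genotypes
$\tilde G_{ij}$ are drawn i.i.d. from $N(0, h^2/|S|)$ or from a Laplace
with scale $b = \sqrt{h^2/(2|S|)}$ — read so that the Laplace variance
$2b^2 = h^2/|S|$ matches the Gaussian case at equal heritability, which
is what makes the two effect distributions comparable. The liability is
$y_i = \sum_{j \in S} w_j \tilde G_{ij} + \epsilon_i$ with
$\epsilon_i \sim N(0, 1-h^2)$; individuals above the **empirical**
$(1-K)$ liability quantile are cases, so the case count is exactly
$\mathrm{round}(K n)$ in every finite sample (a theoretical-quantile
threshold would only achieve this in expectation). Default prevalence
$K = 0.30$; heritabilities of interest are 0.5 and 0.8; causal sets of
30/300/3000 SNPs placed genome-wide or within one region.

The composite (COMP) model is a synthetic stand-in for architectures
with non-additive structure: the causal set is partitioned into equal
thirds contributing additive terms, dominant-coded terms
($1\{G\ge1\}$, standardized), and pairwise interaction terms over
consecutive pairs of the third subset; the summed genetic score is then
rescaled empirically so its population variance is exactly $h^2$ before
adding noise and thresholding. The equal-thirds split and the empirical
rescaling are this package's own committed choices for a composite
architecture, not a canonical form.

Standardization throughout uses the population (divide-by-$n$) SD, so a
standardized column has exactly unit variance on its fitting rows and the
variance bookkeeping $\mathrm{Var}(\sum_j w_j \tilde G_{ij}) \approx h^2$
is exact in expectation. Missing genotypes are mean-imputed with means
learned on training rows only.

# Evaluation

`auc()` is the Mann-Whitney estimator (half credit for ties) computed
from rank sums. `partial_auc()` integrates the empirical ROC curve over
false-positive rates in $[0, 0.1]$ — specificities 90–100%, the clinically
useful corner — by clipping each ROC segment to the window; it is reported
**unnormalized** (maximum 0.1), with McClish standardization available as
an option. Over the full window it reproduces `auc()` exactly, ties
included. Uncertainty on replicate means uses a nonparametric bootstrap
(`bootstrap_sd_of_mean()`, default $10^5$ resamples).

`max_achievable_auc()` answers "how good could any genotype score be?":
under the LTM no score can beat the true genetic liability $g$, so the
ceiling is the AUC of $g$ itself. It is estimated by Monte Carlo
($10^6$ draws by default) and cross-checked against a deterministic
double numerical integral of $P(g_{case} > g_{control})$ over the exact
conditional densities; the two agree within 0.005. A third, cruder
normal-theory approximation (treating $g\,|$ case status as Gaussian with
truncated-normal moments) is also reported: it is accurate at moderate
$h^2$ but biased low by about 0.01 at $h^2 = 0.8$, which is why the exact
integral — not the normal approximation — serves as the cross-check. At
$K = 0.30$ the ceilings are 84.1% ($h^2 = 0.5$) and 94.1% ($h^2 = 0.8$).

# Scenario runner and problem sizes

`run_scenario()` wires the pieces together: one genotype panel per
scenario (reused across replicates, as one real panel would be), a fresh
phenotype per replicate, a uniform train/test split (the test set is
everyone not in training), each method fitted on training rows and scored
on test rows. All randomness derives from one master seed; a
`scenario_result` is a pure function of its spec, and `report_scenario()`
writes raw rows, summaries and a manifest sufficient to reproduce them
byte-for-byte.

The package's own headline experiment — run by `test-acceptance.R` — uses
$n = 3000$ individuals ($2500$ training), $p = 5000$ SNPs in 50-SNP
blocks with $\rho = 0.6$, 30 causal SNPs at $h^2 = 0.8$, and 20
replicates (10 for the ceiling-comparison arm, which averages a less
noisy quantity). CMSA there uses $K = 4$ folds, 100-point paths and
`dfmax = 1000`; these desk-scale settings were chosen so a full run of
both arms completes in minutes on one core while preserving the
$n/p$ ratio and causal fraction that drive the phenomena. Observed
behavior matches the published pattern directionally: when the causal
SNPs share one LD block, joint estimation beats `C+T-max` (about 0.86 vs
0.83 mean AUC here); with genome-wide causal SNPs PLR climbs to within
0.05 of the 0.941 ceiling.

# Numerical and degenerate-input conventions

* Constant columns: standardization refuses them by name; inside the
  solver a fold-constant column is centered to zero and can never
  activate. Monomorphic SNPs after triple encoding are flagged the same
  way.
* Separation in single-SNP logistic fits: score-test fallback (above).
* P-values are clamped into `(0, 1]`; clumping correlation against a
  constant column is treated as zero.
* Ties: clumping priority (P-value, position, column index); `C+T-max`
  threshold (larger $p_T$); CMSA winner (smaller deviance, larger
  $\lambda$, larger $\alpha$). All are deterministic.
* PLINK 1 I/O is bit-exact: SNP-major 2-bit codes, `ceil(n/4)` bytes per
  SNP, missingness preserved; fractional (imputed) matrices refuse to be
  written to .bed.

# What the synthetic results do not show

The simulator's LD is blockwise-stationary and its effects sit directly
on genotyped SNPs; real panels have long-range LD, structure, and causal
variants tagged only imperfectly. Passing tests here therefore establish
correctness of the machinery and the direction of method differences
under controlled architectures — not the absolute AUC one should expect
on any real cohort. Real-data protocol features that need external
inputs (QC pipelines, population-structure correction, summary-statistic
ingestion) are deliberately out of scope.
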