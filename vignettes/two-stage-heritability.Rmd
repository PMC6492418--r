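---
title: "Two-stage SNP-heritability estimation: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage SNP-heritability estimation: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseherit)
```

## The model and the two heritability definitions

The phenotype of $m$ unrelated individuals genotyped at $n$ biallelic SNPs
($m \ll n$) is modelled as the sparse linear system

$$ y = W u^* + e, \qquad e \sim \mathcal N(0, \sigma_e^2 \mathbb I_m), $$

where $W$ is the standardized genotype matrix,
$W_{ij} = (Z_{ij} - 2p_j)/\sqrt{2 p_j (1 - p_j)}$ for allele counts
$Z_{ij} \in \{0,1,2\}$ and sample allele frequency $p_j$, and $u^*$ has $s
\le n$ nonzero entries (the "causal" SNPs, meaning SNPs with nonzero
effects, with support $M_0$). Two standard readings of this model lead to
two heritability definitions:

* **Fixed effects.** Genotype rows are i.i.d. with covariance $\Sigma$ and
  $u^*$ is a fixed vector. The total genetic variance is
  $\tau^2 = u^{*\top} \Sigma\, u^*$ and
  $h^2_{\mathrm{fixed}} = \tau^2 / (\tau^2 + \sigma_e^2)$.
* **Random effects.** The nonzero effects are i.i.d. $\mathcal N(0,
  \sigma_u^2)$ and $W$ is fixed;
  $h^2_{\mathrm{rand}} = s\sigma_u^2 / (s\sigma_u^2 + \sigma_e^2)$.

For standardized SNPs ($\mathrm{diag}(\Sigma) = 1$) and independent
zero-mean effects, $\mathbb E_{u^*}(u^{*\top}\Sigma u^*) = s \sigma_u^2$, so
the two definitions coincide; the test suite exercises this equivalence by
Monte Carlo, both on the quadratic form itself and by checking that the two
estimator branches agree on average on simulated cohorts.

## Why two stages, and why a sample split

With $n$ in the tens of thousands and $m$ in the hundreds or low thousands,
variance-component estimators computed on **all** SNPs are approximately
unbiased but very variable; when most SNPs carry no effect, restricting
estimation to a well-chosen subset shrinks the standard error dramatically.
The package therefore:

1. randomly splits the cohort into halves (`split_sample()`);
2. selects a SNP subset $\hat M$ on half 1 by cross-validated elastic net
   (`select_model()`);
3. estimates variance components on half 2 restricted to $\hat M$, under
   both readings of the model (`mom_estimate()`, `reml_fit()`).

Selection and estimation must see **independent** samples: a model chosen to
fit half 1 fits half 1 too well, and re-using those samples inflates the
apparent genetic variance. The suite demonstrates the direction of this bias
with an internal hook that deliberately estimates on the training half. With
the split, even a selection containing many redundant SNPs does not
overestimate — the redundant coefficients carry no signal on the held-out
half.

The price of the split is that each stage sees only $m/2$ samples; the
variance reduction from sparsity far outweighs this on sparse traits.

## Stage 1: elastic net, cross-validation, and the one-SE rule

Stage 1 minimizes

$$ \frac{1}{2m_1}\lVert y^{(1)} - W^{(1)} u\rVert_2^2
   + \alpha\lambda \lVert u\rVert_1
   + \tfrac{1-\alpha}{2}\lambda \lVert u\rVert_2^2 $$

over a grid of mixing weights $\alpha \in (0, 1]$ and a 100-point geometric
$\lambda$ path from $\lambda_{\max}(\alpha) = \max_j |(1/m_1) w_j^\top
y^{(1)}|/\alpha$ down to $10^{-4}\lambda_{\max}$. The $\ell_1$ part prunes,
the ridge part keeps groups of correlated SNPs together, which matters
because linkage disequilibrium makes neighbouring columns of $W$ strongly
correlated. The default grid $\Omega = \{0.001, 0.01, 0.1, 0.5, 1\}$ spans
near-ridge to lasso; `alpha_grid_realdata()` provides a near-ridge preset
($3\times10^{-5}$ to $10^{-3}$) for strongly polygenic traits. For each
$\alpha$, 10-fold cross-validation (folds fixed across the path) yields mean
held-out MSE and its standard error; the final $\alpha$ is the one whose
path attains the smallest CV MSE.

**Direction of the one-standard-error rule.** Within one SE of the minimum
MSE the data cannot distinguish the candidate models, and the rule must pick
one end of that plateau. Picking the *largest* such $\lambda$ (the
conventional reading) yields the sparsest defensible model — but SNPs with
weak effects are the first ones a heavier penalty drops, and each dropped
causal SNP removes its variance from the stage-2 estimate, biasing the
heritability downward. Picking the *smallest* such $\lambda$ keeps every
model the CV cannot reject and retains those weak effects, at the cost of a
larger selected set; the held-out estimation stage neutralizes the extra
false positives, which carry no signal on half 2. In replicate simulations
(exercised in the acceptance suite) the small-$\lambda$ choice leaves the
two-stage estimator nearly unbiased with replicate spread at the level of
the oracle that knows the true support, whereas the conventional choice
underestimates on sparse architectures. The package therefore defaults to
`one_se_direction = "dense"` and exposes `"sparse"` for users who want the
conventional rule.

**Numerical contract.** The returned coefficient vector of every single-fit
(`fit_elastic_net()`) satisfies the stationarity (KKT) conditions of the
objective above to a subgradient residual below $10^{-6}$; the fit is
produced by a warm-started coordinate-descent path followed by a polishing
sweep that enforces this tolerance directly, and single-column designs use
the exact soft-threshold closed form. An empty selection ($\hat n = 0$) is
legal and flagged; the pipeline then reports the lower boundary value.

## Stage 2, fixed-effect branch: method of moments

On $(y^{(2)}, W^{(2)}_{\hat M})$, with $m_2$ samples and $\hat n$ selected
SNPs, define $S = (1/m_2) W^\top W$ and the spectral summaries
$d_1 = \mathrm{tr}(S)/\hat n$ and
$d_2 = \mathrm{tr}(S^2)/\hat n - \mathrm{tr}(S)^2/(\hat n m_2)$
(the subtraction removes the Wishart noise term, making $d_2$ consistent for
the mean squared eigenvalue of the population covariance). The estimators

$$ \hat\tau^2 = \frac{d_1\lVert W^\top y\rVert_2^2
     - \hat n d_1^2 \lVert y\rVert_2^2}{m_2 (m_2+1)\, d_2}, \qquad
   \hat\sigma_e^2 = \Bigl(1 + \frac{\hat n d_1^2}{(m_2+1) d_2}\Bigr)
     \frac{\lVert y\rVert_2^2}{m_2}
     - \frac{d_1 \lVert W^\top y\rVert_2^2}{m_2 (m_2+1)\, d_2} $$

are moment-based, need no sparsity assumption, remain defined when $\hat n >
m_2$, and handle correlated SNPs through $d_1, d_2$. Two spellings of this
estimator pair circulate that differ in a $d_2$ power and in a $1/m_2$
versus $1/\hat n$ factor; only the form above is dimensionally consistent,
and the Monte-Carlo unbiasedness check in the acceptance suite (identity
covariance, known $\tau^2 = \sigma_e^2 = 1$, both $\hat n < m_2$ and $\hat n
> m_2$) confirms it as the correct default. The other spelling remains
available as `formula = "literal"` for comparison. When $m_2 > \hat n$ with
full column rank these estimators essentially reproduce ordinary least
squares, and $\hat\tau^2 + \hat\sigma_e^2$ tracks the total sample variance
of $y^{(2)}$.

$y^{(2)}$ is mean-centered (or covariate-projected) before the norms are
formed, since the formulas assume a zero-mean response. The standard error
of $\hat h_{\mathrm{fixed}}$ is a nonparametric bootstrap over the
individuals of half 2 (default 200 resamples), as no closed-form SE
accompanies the estimator; a calibration test checks the bootstrap SE
against the replicate-to-replicate spread on simulated data.

## Stage 2, random-effect branch: single-component GREML

The random-effect branch fits $y^{(2)} \sim \mathcal N(Cb,\; \sigma_g^2 K +
\sigma_e^2 \mathbb I)$ by restricted maximum likelihood, with $K = (1/\hat
n) W^{(2)}_{\hat M} W^{(2)\top}_{\hat M}$ the genetic relationship matrix of
the selected SNPs and $C$ the intercept plus any covariates. Because there
is a single kernel, the REML problem is effectively one-dimensional:

1. project the fixed effects out (error-contrast basis via QR);
2. eigendecompose the projected kernel once;
3. profile the restricted likelihood over $h = \sigma_g^2/(\sigma_g^2 +
   \sigma_e^2)$ on a grid of step 0.01 over $[10^{-6}, 1 - 10^{-6}]$,
   followed by golden-section refinement to $10^{-10}$.

This is deterministic, needs no convergence tuning, and is directly
checkable against a brute-force grid over $h$ — the acceptance suite
verifies agreement to $|\Delta h| \le 2\times10^{-3}$ on seeded instances
and that the returned optimum dominates every grid value. A kernel whose
eigenvalue spread is numerically zero makes only $\sigma_g^2 + \sigma_e^2$
identifiable and is rejected with an explicit error. The interior bounds
$[10^{-6}, 1-10^{-6}]$ keep the profiled likelihood finite; the reported
point estimate is clipped afterwards (below).

The standard error of $\hat h_{\mathrm{rand}}$ comes from the delta method:
$\mathrm{SE} = \sqrt{g^\top \mathcal I^{-1} g}$ with $g = (\sigma_e^2,
-\sigma_g^2)/(\sigma_g^2+\sigma_e^2)^2$ and $\mathcal I$ the
average-information matrix at the optimum (observed information available
via `info = "observed"`).

## Clipping and reporting

True heritability lies strictly inside $(0,1)$, so raw ratios at or outside
the boundaries are pinned to $0.0001$ or $0.9999$ and flagged
(`clipped = TRUE`); the clamp is closed at the boundaries so downstream
reports never contain unattainable values. Both branches always run; the
random-effect estimate is the headline number, since the fixed-effect
branch grows unstable when $n$ is very large and SNPs are correlated. Empty
selections are reported at the lower boundary with an explicit flag rather
than as an error.

## The synthetic cohort generator

`simulate_genotypes()` draws allele frequencies uniformly from
`maf_range` (default $U(0.05, 0.5)$ — common variants after a MAF filter)
and, per LD block of `ld_block_size` SNPs (default 100), two latent Gaussian
haplotype processes per individual with AR(1) correlation `ld_rho` (default
0.5) across SNPs, each thresholded at the allele-frequency quantile and
summed. Marginal genotype frequencies therefore follow Hardy–Weinberg
proportions exactly, while neighbouring SNPs are correlated with smoothly
decaying strength, and blocks are independent. Effects put $s$ nonzero
entries at uniform positions with variance $1/s$ each, so the expected
total genetic variance is 1 at every sparsity level and the expected
heritability at noise level $\sigma_e^2$ is $1/(1+\sigma_e^2)$. The
per-cohort truth is summarized by
$\tilde h^* = (\lVert Wu^*\rVert^2/m) / (\lVert Wu^*\rVert^2/m +
\sigma_e^2)$, whose replicate spread at cohort scale is negligible.

What the generator does **not** emulate: population structure and
relatedness, selection pressure on allele frequencies, realistic
recombination-map LD decay, genotyping error, and missingness patterns
(missing calls can be injected separately, and the QC + mean-imputation
path is tested on them). Passing tests on these cohorts therefore validate
the estimators under the model's own assumptions, not robustness to
confounding by structure.

## Quality control and covariates

`qc_filter()` retains SNPs with call rate $\ge 99\%$, MAF $\ge 1\%$ and
Hardy–Weinberg exact-test $p \ge 10^{-6}$ (the exact test enumerates the
conditional heterozygote distribution; standard, non-mid p-value).
Standardization uses allele frequencies from the full QC'd sample **before**
splitting, so both halves share identical design columns; missing genotypes
become 0 on the standardized scale (mean imputation). Covariates are
projected out of both $y$ and every column of $W$ before the split, and the
effective sample size $m - q$ is reported; projecting $W$ as well as $y$
keeps the two stages consistent with each other.

## Problem sizes and reproducibility

Replicate studies in the tests and the acceptance script run at desk scale:
cohorts up to $m = 1000 \times n = 10000$, 20–30 replicates, and a reduced
tuning grid for the two-stage replicates ($\alpha \in \{0.1, 0.5, 1\}$,
50-point $\lambda$ paths) — pilot runs select $\alpha = 1$ on these sparse
scenarios under either grid, so the trim does not change the selected
models. The full-size presets (`scenario_preset(..., full_scale = TRUE)`,
$n = 10^5$) use the same code paths. Every random draw descends from one
master seed through `derive_seeds()`, so each replicate is individually
reproducible and identical inputs plus seed give byte-identical reports.

## Known limitations

* The estimated quantity is the genetic variance attributed to the
  *selected* SNPs: when selection misses weak causal variants, the estimate
  is a lower bound for the SNP heritability (the dense one-SE rule
  mitigates but cannot eliminate this).
* A single variance component: no partitioned heritability, no gene–gene or
  gene–environment terms, no liability-scale transformation for
  case–control traits.
* Sample-level QC (relatedness, heterozygosity outliers) is out of scope;
  the generator produces unrelated individuals, and related samples would
  violate the REML independence assumptions quietly.
* The fixed-branch bootstrap SE assumes exchangeable individuals and
  becomes unreliable when more than half the resamples are degenerate
  (reported as missing with a warning).
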