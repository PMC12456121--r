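---
title: "Methods: multi-environment genomic prediction with spatial adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-environment genomic prediction with spatial adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menvgp)
```

## Scope

`menvgp` implements a two-stage analysis of multi-environment field trials
of inbred lines:

1. **Stage 1 (per environment):** plot phenotypes from a row-column trial
   are adjusted for smooth spatial field variation with a P-spline
   (PS-ANOVA) mixed model, yielding one adjusted genotype mean (BLUE) per
   line and environment.
2. **Stage 2 (across environments):** the line-by-environment BLUE matrix
   is analyzed with Bayesian whole-genome regression models that share
   information through a genomic relationship matrix and, optionally,
   through environmental covariates, and are evaluated with sparse-testing
   cross-validation.

A synthetic-data generator with known breeding values, spatial surfaces and
heritabilities closes the loop: every estimator in the package can be
checked against simulated truth.

## Marker quality control and kernels

`qc_markers()` applies three filters in order: markers with minor allele
frequency at or below 0.05 are removed; markers with a missing-genotype
rate at or above 0.10 are removed; the remainder is pruned for pairwise
absolute correlation at or above 0.99. Pruning uses a greedy left-to-right
scan over marker order in which the later marker of an offending pair is
dropped. Whether such pruning should be windowed or genome-wide is a
modeling choice; the greedy genome-wide scan is the declared behavior here
and is deterministic in marker order while being invariant to line order.
Both frequency thresholds are deliberately inclusive.

`center_standardize()` mean-imputes residual missing dosages per marker,
centers each marker column and scales it by its population (divide-by-n)
standard deviation. The genomic relationship matrix is then
\(K = W W^{\top} / p\) over the \(p\) retained markers
(`grm_vanraden()`). Column centering makes the grand sum of \(K\) zero,
and the construction guarantees symmetry and positive semi-definiteness up
to floating-point error.

The environment kernel \(\Omega\) (`ec_kernel()`) is built the same way
from the environments-by-covariates table: covariates are centered and
scaled across environments and \(\Omega = C C^{\top} / q\). Constant
covariates are rejected rather than silently dropped.

Lines missing in two or more environments are excluded;
a remaining missing BLUE is imputed as the unweighted mean of the
adjusted means of the `k = 20` most related observed lines in that
environment (`impute_phenotypes_by_kin()`), ties broken by line order.

## Spatial adjustment (PS-ANOVA)

For one environment the plot model is

\[ y = \mathbf{1}\mu + X_s\beta_s + Z_s s + Z_r u_r + Z_c u_c + Z_g g +
\varepsilon , \]

where \(X_s = \{1, r, c, rc\}\) holds the non-penalized surface terms on
centered, scaled coordinates and \(Z_s\) collects five penalized blocks:
a row smooth \(f_1(r)\), a column smooth \(f_2(c)\), two
linear-by-smooth interactions \(h_3(r)\,c\) and \(h_4(c)\,r\), and a
smooth-by-smooth tensor block \(f_5(r,c)\) (row-wise Khatri-Rao product
of the marginal bases). Each block is a cubic B-spline basis with a
second-order difference penalty, rotated into its penalty eigenbasis so
that it enters the mixed model with i.i.d. random coefficients. Random
row and column factor effects pick up discontinuous lane effects, and the
genotype enters as a fixed effect with sum-to-zero contrasts.

Variance components are estimated by REML using fixed-point updates on
the smoothing ratios \(\lambda_k = \sigma^2_\varepsilon / \sigma^2_k\)
(Schall/SAP-style: \(\sigma^2_k = \hat u_k^{\top}\hat u_k /
\mathrm{ED}_k\) with \(\mathrm{ED}_k\) the effective dimension of block
\(k\) on Henderson's equations), monitored by the restricted
log-likelihood with tolerance \(10^{-6}\) and at most 200 iterations.
An EM variant was prototyped and discarded: it crawls near variance
boundaries, while the fixed-point updates converge in tens of iterations
and were monotone in the REML objective in all tested conditions.

The reported BLUE is the genotype effect plus the mean non-genetic fitted
value over plots, so adjusted means sit on the same scale as raw genotype
means; correspondingly, simulated spatial surfaces are centered to mean
zero, which keeps the environment intercept identified.

## Prediction models

All stage-2 models act on the \(n \times J\) BLUE matrix (lines by
environments), records in environment-major vec order, with missing
cells predicted by data augmentation.

* **Single-environment GBLUP** (`fit_gblup_single_env()`):
  \(y = \mathbf{1}\mu + g + \varepsilon\), \(g \sim N(0, K\sigma^2_g)\).
* **Reaction norm / genotype-by-covariate** (`fit_gxc()`): five random
  terms over the stacked records — genetic main effect
  (\(J_J \otimes K\)), environment main effect (\(I_J \otimes
  \mathbf{1}\mathbf{1}^{\top}\)), environmental-covariate effect
  (\(\Omega \otimes \mathbf{1}\mathbf{1}^{\top}\)), and the two Hadamard
  interactions (\(I_J \otimes K\) and \(\Omega \otimes K\)) — plus a
  homogeneous residual. The covariate term is treated at the environment
  level (its row kernel is the all-ones kernel), so it shifts whole
  environments; the interaction term \(\Omega \otimes K\) lets those
  shifts differ per line.
* **Marker-by-environment interaction** (`fit_mxe()`): a main genetic
  effect shared by all environments (\(J_J \otimes K\), variance
  \(\sigma^2_{u_0}\)) plus per-environment specific deviations (one
  variance each), with per-environment intercepts. The equivalent ridge
  parameterization in marker space is provided as a closed-form oracle
  (`mxe_ridge_blup()`); the mapping is \(\sigma^2_u = p\,\sigma^2_b\)
  under \(K = WW^{\top}/p\), which the package verifies by a
  dual-parameterization equivalence test.
* **Multi-trait models** (`fit_mtm()`): \(Y = \mathbf{1}\mu^{\top} + U
  (+ F) + E\) with \(\mathrm{vec}(U) \sim N(0, \mathbf{E} \otimes K)\)
  for an unstructured \(J \times J\) genetic covariance \(\mathbf{E}\)
  (MTM1), optionally plus \(\mathrm{vec}(F) \sim N(0, \mathbf{F} \otimes
  I)\) capturing genetic variability not tracked by markers (MTM2). The
  off-diagonals of \(\mathbf{E}\) are free (unstructured) covariances:
  nothing constrains environments to be exchangeable.

## Posterior computation

A single Gibbs engine (`gibbs_multikernel()`) serves the kernel models.
Every random term has separable covariance \((\text{col} \otimes
\text{row})\,\sigma^2_t\); rotating the residual into the term's
eigenbasis makes all coefficient full conditionals independent normals.
Scalar variances receive scaled inverse-chi-square updates with prior
degrees of freedom \(d_0 = 5\) and scales set so the prior mode assigns
half the phenotypic variance to the model, split equally over terms and
adjusted by each kernel's mean eigenvalue. Missing cells are redrawn from
their predictive distribution each sweep, so held-out cells never enter
the likelihood of the observed data.

The multi-trait sampler updates \(\mathbf{E}\) (and \(\mathbf{F}\)) from
inverse-Wishart full conditionals. The prior is
\(\mathbf{E} \sim IW(\nu_0, S_0)\) with \(\nu_0 = J + 2\) by default and a
diagonal scale chosen so that the implied per-environment marginal — a
scaled inverse-chi-square with \(\nu_0 - J + 1\) degrees of freedom and
mode \(S_{0,jj}/(\nu_0 - J + 3)\) — has its mode at the same share of
phenotypic variance that the engine's scalar priors use. Both \(\nu_0\)
and the scale diagonal are configurable (`mcmc_config(iw_df =, iw_scale
=)`). Setting \(\nu_0 = d_0 + J - 1\) makes the per-environment marginal
*identical* to the engine's scaled inverse-chi-square prior, and at
\(J = 1\) the whole prior coincides with it — that matched setting is
what lets the degenerate reduction "MTM1 at \(J=1\) equals
single-environment GBLUP" hold within Monte Carlo error. The choice
matters because with weakly informative data the genetic/residual split
is poorly identified, so prior differences surface directly in
heritabilities and genetic correlations: the default prior's mild
concentration of correlations near zero biases estimated
between-environment correlations downward by roughly 0.1 in the packaged
recovery simulations, a property of the model class under flat
likelihoods rather than of the implementation.

Chains default to 20 000 iterations, 8 000 burn-in, thinning 5. A
closed-form BLUP oracle (`blup_closed_form()`) solves any model in the
family exactly at fixed variances and anchors the engine's correctness
tests.

Posterior summaries: per-environment genomic heritability
\(\sigma^2_g / (\sigma^2_g + \sigma^2_\varepsilon)\) computed per sample
and averaged (`heritability()`); between-environment genetic correlations
as the posterior mean of \(\mathrm{cov2cor}(\mathbf{E})\) with unit
diagonal (`genetic_correlations()`); variance proportions as
posterior-mean variances over their total (`variance_proportions()` —
meaningful because every kernel has unit average diagonal).

## Cross-validation

`make_cv_plans()` builds three masking schemes with a 20% line fraction:
*single_env* and *CV1* hide the test lines everywhere (new, untested
lines), *CV2* hides each test line only in a random nonempty proper
subset of its observed environments (sparse testing — every test line
keeps at least one observed environment). Prediction happens through the
same data-augmentation path as fitting, so masked cells cannot leak.
Predictive ability is Pearson's correlation between predictions and
held-out adjusted means per environment. `compare_models()` runs paired
one-sided Wilcoxon signed-rank and t tests (candidate better than
baseline), exact Wilcoxon for 25 or fewer nonzero untied pairs, and also
reports mean and percent improvement.

## Synthetic data generator

`sim_config()` fixes the study conditions: a few hundred fully inbred
lines (dosages in \{0, 2\}), thousands of independent biallelic SNPs with
uniform allele frequencies, \(J\) environments with breeding values drawn
from \(\mathrm{vec}(U) \sim N(0, \Sigma_E \otimes K)\), complete-block
row-column layouts with replicate bands, a smooth centered spatial
surface scaled to a target standard deviation, i.i.d. replicate effects,
and a configurable fraction of missing line-by-environment cells (with a
guard that no line goes missing in two or more environments, mirroring
the exclusion rule of the analysis). The residual variance in environment
\(j\) is set to \(R \cdot \mathrm{var}(u_j)(1 - h^2_j)/h^2_j\) over
\(R\) replicates, so the target heritability holds at the level of line
means *by construction*.

The generator is intentionally idealized: markers are in linkage
equilibrium, surfaces are smooth and additive, residuals are Gaussian and
homoscedastic within environment. It is a calibration instrument for the
estimators, not a biological simulator, and its defaults are fixed study
conditions rather than tuning knobs.

## Numerical choices and limitations

* Kernel eigendecompositions drop eigenvalues below a relative tolerance;
  the multi-trait sampler instead ridge-stabilizes \(K\) (default
  \(10^{-6}\)) because it needs \(K^{-1}\).
* The spatial REML objective is monitored, not line-searched; a
  non-convergence warning propagates through `extract_blues()`.
* Heritability and variance-proportion summaries assume kernels with unit
  average diagonal; supplying kernels on other scales changes their
  interpretation.
* With weak kinship structure (near-identity \(K\)) the genetic/residual
  decomposition is only weakly identified; posteriors then reflect the
  priors substantially, which is a property of the model class, not of
  the implementation.
* Runtime is dominated by the per-iteration eigenbasis rotations; the
  intended scale is hundreds of lines and a handful of environments.

## Reproducibility

Every stochastic function takes an explicit seed (via `sim_config()`,
`mcmc_config()` or a function argument) and is deterministic given it.
The YAML-driven pipeline (`run_pipeline()`) fans one global seed out to
fixed per-stage offsets and writes a structured log (stage, seed, wall
time, input hashes), so re-running an identical configuration reproduces
identical artifacts.
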