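---
title: "A Bayesian multi-trait multi-environment mixed model for breeding trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian multi-trait multi-environment mixed model for breeding trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Plant-breeding programs evaluate sets of candidate genotypes in comparative
trials repeated across sites, usually as randomized complete block designs
(RCBD), scoring several correlated traits per plot — here, grain yield (GY,
kg/ha) and days to flowering (FL) of flood-irrigated rice lines. Two
questions dominate: how much of the observed variation is genetic (and hence
selectable), and whether genotypes re-rank across environments
(genotype-by-environment, G×E, interaction). Multi-trait multi-environment
(MTME) mixed models answer both jointly, but their likelihood surfaces are
hard for REML-type algorithms at small trial sizes; a fully Bayesian
treatment by MCMC is a robust alternative and yields exact finite-sample
credibility statements for derived quantities such as heritability.

## The model

For the trait vector $y_{iek} \in \mathbb{R}^T$ of genotype $i$ in block $k$
of environment $e$,

$$
y_{iek} = \beta_{e} + r_{ek} + g_i + u_{ie} + \varepsilon_{iek},
$$

with

* $\beta_e$ — fixed environment×trait cell means (no intercept/contrast
  coding: one mean per cell, which is also what the field reports);
* $r_{ek} \sim N_T(0, \Sigma_{r,e})$ — block (replication) effects, nested
  within environment;
* $g_i \sim N_T(0, \Sigma_g)$ — genotype main effects, shared across
  environments;
* $u_{ie} \sim N_T(0, \Sigma_{int,e})$ — per-environment genotype
  deviations, the G×E term (full model only);
* $\varepsilon_{iek} \sim N_T(0, \Sigma_{\varepsilon,e})$ — plot residuals.

All covariance matrices are unstructured $T \times T$ within their scope.
Equivalently, in stacked form $y = X\beta + W_1 r + W_2 g + W_3 u +
\varepsilon$; `assemble()` builds these incidence matrices explicitly with a
deterministic observation ordering (environment, block, genotype, trait
label) so chains are reproducible across platforms.

Three structural choices deserve comment, because the written form of such
models in the literature is often more general than the data can support:

* **Blocks and residuals are block-diagonal by environment.** Replications
  and plots are physically distinct per site, so cross-environment block or
  residual covariances are inestimable from a trial network of this shape;
  we set them to zero structurally rather than asking the sampler to wander
  over unidentified dimensions.
* **The genetic covariance across environments is carried by the shared
  main effect.** We parameterize genotype effects as main + per-environment
  deviation rather than one unstructured $(E \cdot T) \times (E \cdot T)$
  genetic covariance. This matches how variance tables in the field report
  $\sigma^2_g$ and $\sigma^2_{int}$ separately, keeps every parameter
  identified with only two environments, and implies the per-environment
  genetic variance $\sigma^2_{g,e} = \sigma^2_g + \sigma^2_{int,e}$.
* **There is no free-standing random environment effect.** With two
  environments such a variance would be estimated from two draws;
  environment enters only through the fixed cell means and through the
  structure of the random terms.

### The "null" model and a note on terminology

The *null* variant omits $u_{ie}$: genotype effects are forced to be
parallel across environments. Comparing full and null fits by DIC is the
package's test for G×E interaction. Sources describing this model family
sometimes call $r$ an "environment" effect and sometimes a "replication"
effect; we adopt the block-within-environment reading throughout, which is
the only one consistent with an RCBD analysis and with labelling
$\sigma^2_r$ a replication variance.

## Priors

All covariance matrices get conjugate inverse-Wishart priors
$\mathrm{IW}(\nu_0, V_0)$, and the cell means independent Gaussians with a
large variance ($10^8$ on the standardized scale — effectively flat). The
literature for this model family typically names the inverse-Wishart family
without hyperparameters, so defaults must be chosen: we use $\nu_0 = T + 1$
(the smallest integer degrees of freedom giving a proper prior with a
finite mode) and $V_0 = \mathrm{diag}(\widehat{\mathrm{var}}_{phen}/2)$,
i.e. half the empirical phenotypic variance per trait. This is weakly
informative — it says each component contributes some share of the observed
variance — and every choice is overridable through `prior_spec()`.

## Computation

`run_gibbs()` uses a systematic-scan Gibbs sweep: $\beta$, then block,
genotype and interaction effects, then the term covariances, then the
residual covariances, in that fixed order. Because v1 requires balanced
designs, every level of a random term shares the same conditional
precision, so a whole term is drawn with a few matrix operations (a Cholesky
factorization of a $T \times T$ precision and one matrix of standard
normals) rather than a loop over levels — the sampler is pure R and still
fits the default scenario (20,000 iterations) in well under a minute.

Numerical choices:

* Each trait is internally standardized to unit variance; priors supplied
  on the original scale are transformed exactly, and all stored samples,
  posterior means and deviances are back-transformed. Results are invariant
  to trait rescaling (this is tested).
* Conditional precisions are factorized by Cholesky; a failure raises an
  error naming the iteration rather than silently regularizing.
* Retained samples follow `floor((n_iter - burn_in)/thin)` exactly. (The
  10M/500k/10 chain plan sometimes quoted for this model family is
  internally inconsistent with its claimed 50,000 retained samples; we
  report the arithmetic truth, 950,000.)
* All randomness flows through `set.seed(seed)` at the start of a run:
  identical seed, data and configuration give bit-identical chains.

## DIC

Model comparison uses
$\mathrm{DIC} = D(\bar\theta) + 2 p_D$, $p_D = \overline{D} -
D(\bar\theta)$, where $D$ is the *conditional* deviance — $-2 \log$
Gaussian likelihood of the data given the cell means, all random effects
and the residual covariances. This is the DIC reported by the MCMC software
family commonly used for these models; the alternative (marginal) deviance
integrates the random effects out and gives a different, also defensible,
criterion. We follow the conditional convention and record the posterior
mean of every parameter block during sampling so $D(\bar\theta)$ is exact.
The decision rule exposed by `compare_models()` prefers the full model when
$\mathrm{DIC}_{null} - \mathrm{DIC}_{full} > 2$, the null model when the
difference is below $-2$, and calls the models indistinguishable otherwise.

## Derived genetic parameters

Per retained iteration (so every summary has a full posterior):

* broad-sense plot-level heritability
  $h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_r + \sigma^2_\varepsilon)$,
  where under the full model $\sigma^2_g$ is the main-plus-interaction
  genetic variance for that environment, and under the null model the main
  variance alone. The heritability formula in the field names only a single
  genetic variance even when interaction models are fitted, so a concrete
  rule is required; ours is documented and switchable by fitting the other
  variant.
* genetic correlation between traits from the same genetic covariance
  (main + interaction), clamped to $[-1, 1]$ against floating-point
  overshoot; iterations with a zero variance are excluded and counted.
* genotypic and residual coefficients of variation,
  $CV_g = 100\sqrt{\bar\sigma^2_g}/\bar y$ and
  $CV_e = 100\sqrt{\bar\sigma^2_\varepsilon}/\bar y$, computed from
  posterior means (single-number, table-style); their ratio is the relative
  variation index. The phenotype mean in the denominator is the arithmetic
  mean of the observed values for that trait×environment — the standard
  choice, stated here because published tables do not always say. A
  per-iteration ratio chain is attached for interval statements.
* genotype rankings by posterior-mean genetic value $g_i + u_{ie}$, with
  HPD intervals; ties broken by genotype label.

## Diagnostics

* **Geweke z** compares the first 10% with the last 50% of a chain; the
  variance of each window mean is the spectral density at frequency zero
  from an AR fit with AIC-chosen order (the standard estimator in the
  convergence-diagnostics packages).
* **HPD intervals** use the Chen–Shao empirical method: the narrowest
  window of $\lceil p \cdot n \rceil$ consecutive order statistics, ties
  broken by the lowest start index; both endpoints are observed samples.
* **Posterior mode** is the argmax of a Gaussian-kernel density on a fixed
  512-point grid with Silverman's bandwidth — deterministic given the
  chain.
* **Effective sample size** is $n / (1 + 2\sum_k \hat\rho_k)$ with the
  autocorrelation sum truncated at the first non-positive term.

## The synthetic-data generator

No raw data are deposited for the rice trial the package's default scenario
emulates, so the generator is a first-class module rather than a test
fixture. The `rice` preset fixes the design (25 genotypes × 2 environments
× 3 blocks × 2 traits) and uses the published posterior cell means (GY
4210.91 / 3901.56 kg/ha, FL 99.40 / 76.43 days) as true $\beta$. The
covariance components are the package's own choices, stored once in the
versioned preset `extdata/scenario_rice.json` and not tuned thereafter:
genotype SDs (160 kg/ha, 2.5 d) with correlation 0.4, interaction SDs (120,
1.8) with correlation 0.2, block SDs (60, 0.8), residual SDs (150, 2.2)
with correlation 0.1. These give plot-level $h^2 \approx 0.60$ for GY and
$0.63$ for FL under the full model and a genetic correlation of about 0.33
— mid-range values a breeder would call realistic for advanced comparative
trials.

What the generator does *not* emulate: missing plots and unbalanced
networks, spatial field trends, non-Gaussian traits (counts, scores), and
heavy-tailed measurement error. Passing parameter-recovery tests on this
generator therefore shows the estimator is correct under its own
assumptions — it does not certify performance on messy field data.

## What the tests check, and at what scale

The test suite validates the sampler against independent oracles rather
than against itself: conjugate closed forms (the residual-variance marginal
of a fixed-effects model is inverse-gamma; with a known residual variance
the cell mean is Gaussian), a two-dimensional quadrature posterior on a
six-observation one-way toy, exhaustive-search equivalence for HPD windows,
the sampling distribution of the Geweke score on i.i.d. chains, and the
AR(1) closed form for effective sample size. Parameter recovery runs 10
replicates of the default scenario at 20,000 iterations (burn-in 5,000,
thinning 10 — 1,500 retained samples each) and checks 95% HPD coverage of
every true variance component and cell mean; DIC discrimination runs 10
seeds each of a strong-interaction and a no-interaction scenario at 6,000
iterations. These sizes are deliberate desk-scale choices: large enough for
3-MC-standard-error comparisons, small enough to keep the whole suite in
minutes.

One derivation detail worth recording: for the variance-only conjugate
check, the commonly quoted full conditional
$\mathrm{IW}(\nu_0 + n,\ V_0 + \mathrm{RSS})$ holds *given* the mean;
marginally over a flat cell mean the exact law is
$\mathrm{IW}(\nu_0 + n - 1,\ V_0 + \sum_i (y_i - \bar y)^2)$, and that is
the oracle the tests assert against, since the sampler also averages over
the mean.

## Known limitations

* Balanced, complete designs only; missing cells are rejected at
  validation rather than imputed.
* Single-chain diagnostics (Geweke, ESS); no Gelman–Rubin across multiple
  chains.
* The conditional-vs-marginal DIC choice matters when comparing against
  numbers produced by other software; see above.
* With only two environments the split between $\sigma^2_g$ and
  $\sigma^2_{int,e}$ leans on the prior more than a larger network would;
  coverage tests show it is calibrated at the default scenario's size, but
  users with many environments may prefer a richer genetic covariance
  structure, which this version does not implement.
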