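---
title: "Genetic evaluation of body-weight uniformity: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic evaluation of body-weight uniformity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssDHGLM)
```

## The problem

Fish farmed in groups vary in harvest weight even when they share genes,
tanks and feed. Part of that variation is *micro-environmental
sensitivity*: some genotypes buffer unobserved environmental perturbations
better than others, and their families grow more uniformly. Uniformity is
economically relevant (single harvests, less grading, better welfare) and
is itself partly heritable — but its heritability is small, so the
accuracy of estimated breeding values (EBV) for uniformity is the main
bottleneck for selection. This package implements a single-step genomic
evaluation of uniformity for large full-sib family designs of the kind
used in Atlantic salmon breeding: pedigree (`A`), genomic (`G`) and
combined (`H`) relationship matrices; a double hierarchical generalized
linear model (DHGLM) for the mean and the residual variance of body
weight; derived genetic parameters; masking cross-validation of
predictive ability; and index selection.

## The model

Body weight on the analysis scale (standardized, or log to absorb
mean-variance scale effects) follows the animal model

$$y = \mu + \beta\,\mathrm{age} + \mathrm{tank} + \mathrm{yearclass}
      + a + c + e,$$

with additive genetic effect $a \sim N(0, K\sigma^2_a)$ for $K \in
\{A, H\}$, a full-sib common-environment effect
$c \sim N(0, I\sigma^2_c)$, and residual $e$. The *dispersion* part makes
the residual variance itself genetic:

$$\operatorname{Var}(e_i) = \sigma^2_e \exp(a_{v,i} + c_{v,i}),$$

so an animal with a negative $a_v$ is genetically more uniform. The two
traits $(y, \text{log residual variance})$ are fitted jointly as a
bivariate mixed model on $(y, \psi)$, where

$$\psi_i = \log\hat\sigma^2_{e_i} +
  \frac{\hat e_i^2/(1-h_i) - \hat\sigma^2_{e_i}}{\hat\sigma^2_{e_i}}$$

is the linearized working response built from the current residual
$\hat e_i$, leverage $h_i$ (diagonal of the full mixed-model projection,
fixed plus random) and fitted residual variance $\hat\sigma^2_{e_i}$. The
residual weights are $W = \mathrm{diag}(1/\hat\sigma^2_{e_i})$ for $y$ and
$W_v = \mathrm{diag}((1-h)/2)$ for $\psi$; the two scaled residual
variances of the bivariate system are expected to converge to 1 and are
reported (`scaled_eps`) as a model-adequacy check.

Variance components are estimated with the *sire-dam* parameterization
(genetic effects on parents, each explaining a quarter of the additive
variance), which is less prone to the feedback between an individual's
own EBV and its own squared residual than the animal parameterization.
Predictions for selection candidates use the *animal* parameterization at
those fixed components (`predict_breeding_values()`), mirroring how such
evaluations are run in practice.

## Relationship matrices

* `relationship_matrix()` builds `A` by the tabular method with full
  inbreeding bookkeeping; `relationship_inverse()` gives the sparse
  inverse directly from Henderson's rules. The two are cross-checked in
  the test suite against a gene-dropping identity-by-descent oracle
  (`ibd_relationship()`, compiled, $10^5$ replicate drops).
* `build_genomic_relationship()` computes VanRaden's
  $G = WW'/N$ with $w_{ij} = (x_{ij} - 2p_j)/\sqrt{2p_j(1-p_j)}$; allele
  frequencies come from the currently genotyped animals, and missing
  codes are imputed at $2p_j$ (scaled zero), which preserves zero column
  means. `qc_snps()` applies the standard panel filters sequentially:
  call rate $\ge$ 0.90, Hardy-Weinberg equilibrium ($\chi^2$ test,
  $P \ge 10^{-15}$), minor allele frequency $\ge$ 0.01.
* `build_H_direct()` assembles the single-step matrix with the standard
  block form
  $H_{11} = A_{11} + A_{12}A_{22}^{-1}(G - A_{22})A_{22}^{-1}A_{21}$,
  $H_{12} = A_{12}A_{22}^{-1}G$, $H_{22} = G$; `build_H_inverse()` uses
  the shortcut $H^{-1} = A^{-1} + \mathrm{blockdiag}(0,\, G^{-1} -
  A_{22}^{-1})$. The two constructions are verified against each other to
  $10^{-8}$ elementwise in the tests.
* Before inversion `G` is made compatible with the pedigree base:
  `tune_genomic()` rescales $G^* = a + bG$ so its mean diagonal and mean
  off-diagonal match $A_{22}$ (necessary whenever the genotyped animals
  are a related subset — without it the combined matrix can predict
  *worse* than `A`), and `blend_genomic()` mixes in 1% of $A_{22}$ to
  guarantee full rank. Both are defaults of `evaluation_inverse()` and
  can be switched off.

## Estimation algorithm and numerical choices

`fit_dhglm()` alternates (i) a sparse solve of Henderson's mixed-model
equations for the bivariate system, (ii) one EM-REML update of all
(co)variance components — quadratic forms in the solutions plus
prediction-error traces from the inverted coefficient matrix — and (iii)
a refresh of $\psi$, $W$ and $W_v$. EM steps are extrapolated with a
norm-based Aitken acceleration every five iterations; proposals that
would materially lower the REML log-likelihood are discarded.

Convergence deserves a note. The monitored log-likelihood belongs to a
*working* response that itself changes every iteration, and in these
models the likelihood surface has a nearly flat ridge when the genetic
correlation between the mean and its dispersion approaches 1 (which is
exactly where untransformed body weight sits). On that ridge the
log-likelihood plateaus with oscillations of order $10^{-3}$ while the
components move by far less than their standard errors. The fit therefore
stops when the log-likelihood change falls below `tol` (default $10^{-4}$)
*or* when the relative norm of the per-iteration component update falls
below `comp_tol` (default $10^{-4}$); demanding $10^{-6}$ on the
log-likelihood would ask the criterion to resolve directions that carry
no statistical information. Components are floored at $10^{-8}$,
2x2 covariance blocks are kept positive semi-definite by clipping the
implied correlation at 0.999, and rare fixed-effect levels (fewer than
two records, as can happen in masked subsets) are merged into the
reference level with a warning.

`predict_breeding_values()` iterates only the weights at fixed
components, with a damped (geometric-mean) update of the fitted residual
variances to suppress two-cycles, and accepts a `warm_start` fit whose
per-record variances, leverages and working responses seed the iteration
— cross-validation folds warm-started from the full-data fit typically
need two to four solves.

## Derived parameters

From the converged components (sire-dam scale, $\sigma^2_a = 4\sigma^2_u$):

* $\sigma^2_P = 2\sigma^2_u + \sigma^2_c + \sigma^2_e$, where
  $\sigma^2_e$ is the observation-mean of the fitted per-record residual
  variances (the model has no single residual variance; this scalar
  choice is documented rather than prescribed).
* $h^2 = \sigma^2_a/\sigma^2_P$ and $c^2 = \sigma^2_c/\sigma^2_P$.
* Uniformity variances are estimated on the exponential scale and
  converted by the first-order linearization
  $\sigma^2_{a_v} = (\sigma^2_e)^2\,\sigma^2_{a_v,\exp}$ (exact extended
  conversions exist but add nothing at these magnitudes; the
  linearization is verified against Monte Carlo in the tests).
* $h^2_v = \sigma^2_{a_v} / (2(\sigma^2_P)^2 + 3(\sigma^2_{a_v} +
  \sigma^2_{c_v}))$ and the analogous $c^2_v$ — the denominator is the
  variance of squared phenotypic deviations under normality plus the
  variance of the variance itself.
* $GCV = \sqrt{\sigma^2_{a_v,\exp}}$, the genetic coefficient of
  variation of the residual variance: a scale-free measure of how much
  selection can move uniformity.

## Cross-validation

`make_folds()` partitions the phenotyped animals into ten disjoint,
family-stratified masks. For each fold the masked records are removed,
breeding values are re-predicted by BLUP at the full-fit components, and
predictive ability is the correlation between the masked *genotyped*
animals' adjusted phenotypes ($y^* = \hat a + \hat c + \hat e$, i.e. the
response minus fitted fixed effects, from the full-data fit) and their
predicted breeding values — Pearson for weight; Pearson, Kendall tau-b
and Spearman for uniformity, whose adjusted phenotype is exponentially
rather than normally distributed. The scaled MSEP divides the mean
squared prediction error by the sample variance (divisor $n-1$) of the
fold's adjusted phenotypes. Model differences are judged by
$d \pm 1.96\,\mathrm{SE}_d$ with
$\mathrm{SE}_d = \sqrt{(SD_1^2 + SD_2^2)/k}$. Adjusted phenotypes are
taken from the full-data fit of the same model variant being validated
(self-consistent targets); pooling masked animals per fold, rather than
averaging within families first, is the implemented reading.

## The synthetic-data generator

`sim_config()` defaults emulate a commercial salmon nucleus: 131 sires
by 234 dams (one sire per dam, 1-3 dams per sire), 234 full-sib families
with mean size 15.4 truncated to 4-54 (about 3600 phenotyped fish), 50
genotyped families contributing 21-38 genotyped sibs each plus all
parents (roughly 39% of offspring genotyped), age at measurement spread
over a four-week hatching window, three tanks, and two parental year
classes in a 47/53 ratio. Genetic structure on the (unit-variance)
analysis scale: $\sigma^2_a = 0.3$, $\sigma^2_c = 0.1$, baseline
$\sigma^2_e = 0.5$ (mean realized residual variance about 0.6, hence
$h^2 \approx 0.3$, $c^2 \approx 0.1$), $\sigma^2_{a_v,\exp} = 0.23$
($GCV \approx 0.48$), $r_g(\text{mean, dispersion}) = 0.95$, and
$\sigma^2_{c_v,\exp} = 0.135$ ($c^2_v \approx 0.02$). With
`scale_effect = TRUE` the same model lives on the log scale with
log-scale defaults ($\sigma^2_a = 0.045$, $\sigma^2_{a_v,\exp} = 0.09$,
$r_g = 0$) and observed weight is the exponential — reproducing the
empirical pattern that raw-scale mean and variance are almost perfectly
genetically correlated while log-scale uniformity is nearly independent
of growth.

Two features deserve emphasis:

* **Genetic architecture.** By default (`genetic_architecture =
  "genomic"`) breeding-value pairs are sums of per-SNP effect pairs over
  the gene-dropped panel, so marginally $\operatorname{Var}(a) =
  \sigma^2_a A$ while the markers carry the trait's Mendelian sampling —
  the information single-step evaluation exists to exploit. With
  pedigree-only simulation (used when no genotypes are generated) the
  markers are trait-irrelevant by construction and genomic evaluation
  cannot, and should not, beat pedigree BLUP.
* **Panel size as effective genome segments.** The simulated loci are
  unlinked, so the panel size plays the role of the number of
  *independently segregating genome segments*, not of the SNP count of a
  real array: a real 30k-SNP genome behaves like a few hundred
  independent segments. Simulated panels are therefore chosen in the
  hundreds (default 1000 at full design scale; 200 in the scaled-down
  test designs) to reproduce realistic genomic accuracy; inflating the
  panel would *weaken* the genomic signal, not strengthen it.

What the generator does not emulate: linkage and LD structure (hence no
within-chromosome inheritance correlation), genotyping error and missing
calls (test fixtures plant those explicitly where needed), selection or
overlapping generations, and any non-genetic trends beyond the fixed
effects above. Passing tests on these simulations show the estimator
machinery is correct and well-calibrated under the model's own
assumptions; they do not certify behavior under model misspecification
on real data.

## Problem sizes used in the tests

The test-suite simulations are scaled so the whole suite runs in tens of
minutes on one core: variance-component recovery uses 200 families of 15
(the configuration whose dispersion variance matches the full design)
with 10 seeded replicates; the pedigree-vs-genomic comparisons use 120
families of about 12 (70 sires, roughly 1450 fish) with all families
contributing 8-14 genotyped sibs and a 250-segment panel — chosen from a
power analysis run before the comparison seeds were fixed, since the
genomic advantage for a trait with h²ᵥ of a few percent is undetectable
in much smaller designs — again over 10 replicates; oracle equivalences (gene-dropping vs tabular
A, dense-inverse vs shortcut H, dense GLS vs sparse solver, balanced
closed-form REML vs EM) run at a few hundred animals. These sizes are
the package's standing choices and are fixed in the tests rather than
tuned per run.

## Known limitations

* EM-REML is robust near variance boundaries but slow on flat ridges;
  an average-information update would converge in fewer iterations and
  is a natural extension.
* No standard errors are reported for $h^2_v$ and $GCV$; the sampling
  variance of these ratios requires approximations beyond this package's
  scope, and the cross-validation differences carry their own CIs.
* The sire-dam animal-level EBV used in validation is the parental sum
  $\hat u_s + \hat u_d$; it omits the Mendelian sampling deviation,
  which is precisely why the animal parameterization predicts uniformity
  better and why both are provided.
* Metafounders, unknown-parent groups and large-scale approximations of
  $H^{-1}$ (APY) are out of scope.
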