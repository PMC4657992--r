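---
title: "Multivariate variance decomposition in the classical twin design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate variance decomposition in the classical twin design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The classical twin design compares monozygotic (MZ) pairs, who share
essentially all segregating genes, with dizygotic (DZ) pairs, who share on
average half of them. For $p$ phenotypes measured on both members of a pair,
`twinsem` models the $2p$-vector of a pair as multivariate normal (on the
liability scale for binary traits) with

$$\Sigma_{\text{within}} = \Sigma_A + \Sigma_C + \Sigma_D + \Sigma_E,
\qquad
\Sigma_{\text{cross}} = \alpha_A \Sigma_A + \alpha_C \Sigma_C + \alpha_D \Sigma_D,$$

where $(\alpha_A, \alpha_C, \alpha_D)$ is $(1, 1, 1)$ for MZ and
$(\tfrac12, 1, \tfrac14)$ for DZ pairs, and $A$, $C$, $D$, $E$ are the
additive-genetic, shared-environmental, dominance and non-shared
environmental components. $E$ (which absorbs measurement error) is never
shared across twins, and $C$ and $D$ are not jointly identifiable from
twin-pair data alone.

Each component covariance is parameterized by structure:

* **Cholesky**: $\Sigma_X = L_X L_X^\top$ with $L_X$ lower-triangular —
  $p$ ordered factors per component, positive semidefinite by construction;
  the fullest decomposition of covariance into trait-ordered factors.
* **Independent pathway**: common loading vector(s) per component plus
  trait-specific paths, $\Sigma_X = \Gamma_X \Gamma_X^\top + \mathrm{diag}(s_X^2)$.
* **Common pathway**: latent phenotype(s) with unit variance, themselves
  decomposed into A and E shares, loading on all traits, plus trait-specific
  A and E paths.
* **Saturated**: free mean/threshold per trait per twin order per zygosity
  group and a free $2p \times 2p$ covariance per group — the reference model
  for testing the equality of moments across twin order and zygosity.

### Mixed scales and identification

Continuous traits carry a free mean and free total variance. A binary trait
is the indicator of a latent liability exceeding a threshold $\tau$; its
liability variance is not identified and is fixed at 1 by *deriving* the
trait's non-shared diagonal path as
$e_{ii} = \sqrt{1 - (\text{all other squared row entries})}$, with a smooth
penalty when the remainder would be negative. This removes exactly one free
parameter per binary trait from every structured model — and from every row
of the saturated covariance that involves the trait — so *differences* in
parameter counts between models (the df column of a comparison ladder) are
unaffected. `count_free_parameters()` therefore reports the conventional
nominal counts: $p(p+1)/2$ per Cholesky component, $2pf + 2p$ for an
independent-pathway model with $f$ factor sets, $f(1+p) + 2p$ for a
common-pathway model with $f$ latents. For the four-trait ladder these give
the familiar differences of 10 (AE vs ADE Cholesky), 14 (IP-1), 17 (CP-1)
and 6 (IP-2) relative to the full ADE Cholesky.

Two bookkeeping points are genuinely convention-dependent and we document
ours rather than force agreement with any particular printed table: the
saturated-vs-Cholesky df difference depends on how saturated means,
thresholds and age slopes are counted per group (ours: free means/thresholds
per trait per twin order per zygosity, age slopes shared), and a two-latent
common-pathway model counts $2(1+p) + 2p = 18$ structural parameters here
(df difference 12 vs the full ADE Cholesky), since no rotational constraint
is imposed on the two latents.

Age enters *inside* the model as a fixed linear term on means (continuous)
and on liability means (binary), rather than by pre-residualizing, which
keeps the likelihood correct for pairs with missing co-twins.

## Full-information likelihood

Every pair contributes the likelihood of exactly its observed entries:
observed continuous entries contribute a multivariate-normal density;
observed binary entries contribute the probability of the latent rectangle
consistent with their 0/1 pattern, conditional on the observed continuous
entries; missing entries are marginalized by dropping rows and columns.
Pairs are grouped by zygosity and missingness pattern so each group is
evaluated vectorized.

Rectangle probabilities are the numerical workhorse. Dimension 1 is the
normal CDF; dimension 2 a 96-point Gauss–Legendre rule on the conditioned
inner integral (absolute error $\sim 10^{-7}$); dimensions 3–4 (two binary
traits observed in both twins) use sequential conditioning on a fixed
shifted Richtmyer lattice with antithetic averaging during optimization
(fast, $\sim 10^{-4}$), and the deterministic Miwa grid algorithm for the
final reported $-2\ln L$ ($\sim 10^{-8}$). All point sets are fixed, so
likelihoods are bit-reproducible and never touch the user's RNG stream.

Optimization is quasi-Newton (BFGS) from multiple jittered starts (default
5; data-driven start heuristics, sample moments for the saturated model).
The reflection indeterminacy of path matrices (any factor column may flip
sign) is resolved *after* fitting by canonicalizing column signs so that
diagonals are non-negative, rather than by constraining the search — this
keeps the likelihood smooth at genuinely zero factor variances, which
matters for boundary tests such as dropping dominance. Confidence intervals
are numerical-Hessian Wald intervals on the unconstrained scale,
delta-method transformed for derived quantities (heritabilities, genetic
correlations); profile-likelihood intervals are not implemented.

Model comparison uses the likelihood-ratio test ($\Delta(-2\ln L)$ against
$\chi^2_{\Delta df}$) and AIC $= -2\ln L + 2k$. Variance components sitting
on the boundary of the parameter space distort the $\chi^2$ reference in
both directions, and we use the standard reference regardless, as
comparison tables in this literature conventionally do. Testing *down*
(dropping D when the truth has $d = 0$) is conservative — p-values are
stochastically above uniform, which the test suite checks directly. Testing
a full Cholesky *against the saturated model* is anti-conservative when
true components are at or near zero (the full model cannot spend its
boundary parameters, so the saturated advantage exceeds its nominal df); in
simulation this inflation is negligible for continuous traits at study
scale but becomes visible with liability-threshold traits and a
boundary-true C, and grows with sample size. The step-1 assumption check
should therefore be read with this in mind — `four_step_compare()` reports
it but never treats it as fatal — and under an interior-truth generative
structure the same check is well calibrated. The four-step ladder
(`four_step_compare()`): saturated check and ACE/ADE choice by AIC; drop
C/D; compare against independent- and common-pathway alternatives; then
user-declared reduced submodels expressed as path drop lists such as
`"A[2,1], E[4,3]"`. The selected model is the lowest-AIC candidate not
rejected against the full Cholesky base at $\alpha = 0.05$, ties broken
toward fewer parameters.

## Decomposition quantities

From a converged structured fit: heritability
$h^2_i = \Sigma_{A,ii} / \Sigma_{P,ii}$; the factor-by-trait table of
squared standardized loadings (percent of phenotypic variance per latent
factor); genetic and environmental correlations
$r_{G,ij} = \Sigma_{A,ij}/\sqrt{\Sigma_{A,ii}\Sigma_{A,jj}}$ (structural
zeros reported as 0); and the Cholesky attribution of a target trait's
genetic variance to the factors first loading on each earlier trait
(squared standardized cross-paths, renormalized to 100% across sources plus
the trait-specific factor). The attribution depends on the declared trait
ordering — a known property of Cholesky decompositions — so the report
always carries the ordering. It is one defensible reading of "share of
genetic variance explained by" a correlate; no claim is made that it is the
only one.

## The synthetic cohort generator

`simulate_cohort()` draws per-component factor scores as correlated
multivariate normals with exactly the cross-twin correlations above, mixes
them through the declared path matrices, adds the shared-within-pair age
effect, thresholds binary liabilities, and applies missing-at-random
missingness last. Because the generator *is* the model family, recovery
experiments are unconfounded: estimation error measures the estimator, not
generator/model mismatch.

The defaults emulate the motivating study's conditions and are fixed once:

* 219 MZ + 244 DZ pairs; age 58.39 (SD 11.08) years, shared within pair.
* Four phenotypes in Cholesky order DHEAS, fatigue, depression, CWP
  (chronic widespread pain); depression and CWP binary with prevalences
  30.06% and 19.62%; DHEAS and fatigue continuous on the standardized
  liability scale (the original units are assay/instrument specific; any
  monotone transformation to normality is left to the user).
* Path matrices: the Cholesky factors of the component covariances implied
  by the published heritabilities (74.2, 42.6, 49.9, 70.8%) and the genetic
  and environmental correlation matrices of the final reduced model. This
  structure has exactly seven zero paths — three genetic factors and a
  CWP-specific environmental factor — and unit total variance per trait.
* Small default age slopes (DHEAS declining with age), with binary
  thresholds adjusted so the marginal prevalence is exact under the age
  effect.
* Per-twin record missingness of 0.44, conditional on each pair
  contributing at least one record; this reproduces the study's ratio of
  individuals to pairs (642 records across 463 pairs, i.e. singles in
  roughly 61% of pairs). Conditioning on "pair present in the study" is a
  sampling event independent of trait values, so the mechanism remains MAR.

What the generator does **not** emulate: assortative mating,
gene-environment correlation or interaction, sibling contrast effects,
sex differences (the cohort is all-female by design), age moderation of
variance components, and non-normal measurement error. Passing recovery
tests therefore demonstrate correctness of the estimator under the model's
own assumptions, not robustness of the design to their violation.

## Problem sizes and numerical choices

The test-suite and acceptance experiments use study-scale cohorts
(219 + 244 pairs) for recovery (200 replicates each for univariate
heritability at 0.742 and bivariate genetic correlation at 0.78), reduced
cohorts (80 + 80 or 100 + 100 pairs, 400-1000 replicates) for null
calibration of the LRT, and 25k-50k-pair cohorts for moment-convergence
checks. The full mixed-trait ladder on a default cohort (the `analysis/`
scripts) is the heaviest computation — one to two hours single-threaded,
dominated by the ~80-parameter saturated model over 4-dimensional liability
blocks.

Numerical defaults: optimization lattice 512 points (256 in the ladder
scripts), final likelihoods via the exact integrator; BFGS relative
tolerance $10^{-10}$, maximum 1000 iterations; unit-liability penalty
activates beyond a remainder of $10^{-6}$; tetrachoric correlations are
maximum likelihood with margin-fixed thresholds, solutions flagged at
$|\rho| \ge 0.999$; biserial correlations are full ML (point-polyserial
form); bootstrap CIs (default 1000 resamples, seeded) for tetrachoric,
biserial and all cross-twin cross-trait entries, Fisher-z for plain Pearson.
Negative LRT statistics beyond 0.05 raise an error (optimization failure)
rather than being silently clamped.

## Known limitations

* Wald CIs can be poor near boundaries (heritabilities near 0 or 100%);
  profile intervals would be better there and are not provided.
* The tetrachoric/biserial estimators assume latent bivariate normality;
  with model violation they are merely descriptive.
* Cross-twin cross-trait bootstrap intervals resample pairs within one
  zygosity group; no small-sample continuity corrections are applied.
* The common-pathway implementation supports A+E latent decompositions
  (the configuration the comparison ladder needs), not C/D latents.
* Printed p-values in this package's tables are full precision; when
  matching literature tables note that those are often truncated, not
  rounded, to 3 decimals.
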