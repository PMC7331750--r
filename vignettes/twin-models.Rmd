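---
title: "Variance decomposition in twin designs: models, parameterizations and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance decomposition in twin designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpath)
```

## The twin design and its assumptions

The classical twin design estimates how much of the variation in a trait is
attributable to additive genetic differences (A), to environments shared by
co-twins (C), and to person-specific environments plus measurement error
(E). It rests on three assumptions that this package encodes directly:
monozygotic (MZ) co-twins correlate 1 on A while dizygotic (DZ) co-twins —
including opposite-sex pairs — correlate 0.5; C correlates 1 within every
pair regardless of zygosity (the equal-environments assumption); and E is
uncorrelated between co-twins. For a standardized phenotype the cross-twin
covariance is therefore `a2 + c2` in MZ pairs and `0.5 a2 + c2` in DZ
pairs, which is what makes the components identifiable from two observed
covariances plus the variance.

The multivariate models all reduce to the same block structure. Given
phenotypic component matrices `A`, `C`, `E` (p x p), the twin-pair
covariance per zygosity group is

```
| A + C + E     r A + C   |
| r A + C       A + C + E |         r = 1 (MZ), 0.5 (DZ)
```

`expected_twin_covariance()` computes these blocks exactly for every
generating model; the simulators never touch this algebra (they draw the
latent A/C/E variables directly), so the two routes cross-validate each
other in the test suite.

## Model family

* **Univariate ACE** (`fit_univariate_ace`): components are parameterized
  as unconstrained paths `a, c, e` entering squared, mirroring Mx-style
  path models; no bound constraints are needed, negative paths are
  admissible, and the reported standardized shares `a2/c2/e2` always sum
  to 1. Nested AE/CE/E submodels drop paths; `lrt()` compares them.
* **Sex limitation** (`fit_sex_limitation`): a nested five-group sequence —
  qualitative (sex-specific paths and means, opposite-sex genetic
  correlation free in (0, 0.5)), quantitative (r fixed at 0.5), scalar
  (equal standardized shares, a male variance multiplier), homogeneity
  (everything equated). Qualitative sex differences are modelled by the
  freed opposite-sex genetic correlation; the alternative
  male-specific-factor parameterization is not implemented.
* **Common pathway** (`fit_common_pathway`): one latent factor with its own
  A/C/E drives all indicators; residuals carry indicator-specific A/C/E.
* **Hierarchical** (`fit_hierarchical_model`): a second-order general
  factor above three or more first-order factors; AE by default, because
  in practice shared environment rarely survives at this level in adult
  cognitive data — an ACE variant is available.
* **Cholesky** (`fit_cholesky`): triangular genetic/environmental path
  matrices over explicitly ordered phenotypes; the implied `A = L Lᵀ` is
  positive semidefinite for every parameter value. Entering a general
  cognitive ability composite first apportions each later trait's genetic
  variance into a part shared with it and a unique part. The analysis of a
  latent spatial factor against observed `g` is exposed both as the full
  latent hierarchical fit and as a simplified bivariate observed-composite
  Cholesky; the bivariate form is what the recovery checks exercise,
  because it has an unambiguous parameterization.
* **Path tracing** (`path_trace_genetic_share`): the proportion of a
  trait's genetic variance captured by a common factor,
  `(common_a2 λ²) / (common_a2 λ² + specific_a2)`.

## Identification and parameterization

Latent factor scales are set by fixing every latent variance to 1, not by
marker loadings, so loadings and components are directly standardized and
comparable across models. For factors that carry an A/C/E decomposition
this constraint is built into the parameter space: the paths live on the
unit sphere via spherical coordinates (K - 1 unconstrained angles for K
components), so `a2 + c2 + e2 = 1` holds exactly at every iterate rather
than being enforced by penalty or post-hoc rescaling. Indicator residual
paths are unconstrained and enter squared.

In the CFA engine (`fit_cfa`) residual variances are unconstrained by
default: inadmissible (Heywood) solutions are allowed but flagged, with a
`bounded = TRUE` refit option that moves them to the log scale. The
chi-squared statistic uses the `(N - 1)` multiplier on the ML discrepancy;
the baseline for CFI/TLI is the independence model with free variances
(fitted in closed form). TLI is clipped to [0, 1]; RMSEA is defined as 0
whenever `T <= df` (including `df = 0`); SRMR averages squared
standardized residuals over the unique elements including the diagonal.

## Full-information maximum likelihood

All twin models maximize the sum over pairs of the multivariate-normal log
density restricted to each pair's observed entries. Internally, pairs are
grouped by zygosity and missing-data pattern and reduced to per-pattern
sufficient statistics, so the objective costs O(p³) per pattern
independent of sample size; complete data collapse to one pattern per
group. This is exact FIML under MCAR/MAR and is what makes the
200-replicate coverage and 100-replicate sex-limitation suites affordable.
Missingness in the generator is MCAR, matching the preprocessing
assumption.

Optimization is BFGS (`stats::optim`) with numerical gradients, relative
tolerance 1e-12, and up to 10 jittered restarts on non-convergence, drawn
from the session RNG stream so a seeded pipeline remains reproducible; a
final polish pass re-runs from the optimum. Covariance matrices that fail
a Cholesky factorization during the search receive a large finite penalty
rather than an error. The sex-limitation sequence is fitted
restrictive-to-rich with warm starts from the nested solution, which makes
the -2 log-likelihood chain monotone to optimizer tolerance even when the
opposite-sex genetic correlation sits at its 0.5 boundary.

Profile-likelihood confidence intervals (`likelihood_ci`, `confint`)
re-parameterize the univariate model as (mean, log total variance,
standardized shares) and locate the points where -2 lnL rises by the
chi-squared(1) quantile, clipping to the admissible [0, 1] range and
reporting boundary-stuck profiles as one-sided. Profile intervals were
preferred over bootstrap as the default because they respect the share
constraint and cost a handful of low-dimensional refits.

## The synthetic-cohort generator

Because the motivating study's raw cohort is access-controlled, every
downstream stage is exercised on synthetic cohorts with known generative
structure. The generator emulates: five zygosity groups with realistic
young-adult register sizes (defaults 178 MZm, 169 MZf, 325 DZm, 260 DZf,
398 opposite-sex pairs; ages 21.2 ± 0.53 years), standardized phenotypes
with exchangeable twin order (opposite-sex pairs randomize which member is
male), additive sex and age effects injected after the biometric draw, and
MCAR missingness. Generating values used throughout the tests are the
published point estimates for this domain: a six-test common factor with
ACE = 0.64/0.08/0.28 and loadings spanning 0.54-0.75; a hierarchical AE
structure whose general factor is 84% genetic with first-order R² of
0.79/0.69/1.00 and factor-level specific genetic variances 0.05/0.27/0; a
bivariate Cholesky in which the first trait (70% heritable, a conventional
adult value chosen here) accounts for 55% of the second trait's genetic
variance; sex-specific heritabilities 0.52 (male) and 0.54 (female) with a
shared-environment share of 0.08 for both sexes. Where only ranges are
published (indicator-specific residual composition), the residual of each
indicator is split 20% A / 5% C / 75% E (25/75 in AE worlds) — chosen once
as typical of test-level cognitive data, where specific variance is
dominated by nonshared environment and measurement error.

What the generator does **not** emulate: item-level response processes,
selection or attrition, assortative mating, dominance, gene-environment
interaction or correlation, non-normal score distributions, and
missingness related to ability. Passing recovery tests therefore shows
that the estimators are correct for the assumed data-generating process,
not that real cohort data meet those assumptions.

## Problem sizes and numerical checks

The test suite checks closed-form limits at 50,000 pairs per zygosity
class (tolerance ±0.01, about two Monte-Carlo standard errors), parameter
recovery at 2,000 MZ + 2,000 DZ pairs, the sex-limitation design at the
register group sizes above (100 replicates), profile-CI coverage at 200
replicates, and Monte-Carlo validation of the implied-covariance algebra
at up to 200,000 pairs per group. Univariate shared-environment recovery
is asserted on the mean of 20 replicates at the same design, because the
single-fit sampling SD of the C share at 4,000 pairs is ~0.036 — wider
than the ±0.05 recovery band a single draw is held to. Degenerate inputs
are exercised deliberately: unit loadings with zero specific variance,
boundary second-order loadings (R² = 1), zero-variance phenotypes
(rejected with errors), and cohorts lacking a zygosity group (the
qualitative sex-limitation model is skipped with a warning).

## Known limitations

Standard errors are not reported from the information matrix; interval
estimates come from the profile likelihood (univariate) and would require
a delta-method or profile extension for the multivariate models.
Independent-pathway models exist only implicitly as nesting checks, not as
a first-class fit. The CFA engine deliberately omits robust/categorical
estimators, modification indices and exploratory factor analysis. The
opposite-sex genetic correlation is bounded in (0, 0.5) by construction,
so likelihood-ratio tests against r = 0.5 are boundary tests and
conservative.
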