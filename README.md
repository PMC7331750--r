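# twinpath

Twin-design variance decomposition for multivariate cognitive phenotypes,
in base R.

`twinpath` is for behavioural-genetics researchers who want a transparent,
scriptable implementation of the classical twin analysis toolchain: it
simulates twin cohorts with known genetic architecture, prepares phenotypes
the way twin studies prepare them (composite scoring, age/sex
residualization, one-twin-per-pair selection, distributional screening),
compares confirmatory factor models, and fits the standard biometric model
family — univariate ACE, five-group sex limitation, common pathway,
hierarchical second-order, and Cholesky decomposition — by full-information
maximum likelihood (FIML). Its motivating use case is the genetics of
spatial cognition, where batteries of navigation and object-manipulation
tests are decomposed into shared and test-specific genetic and
environmental variance, but nothing in the package is specific to that
domain.

## The model

The classical twin design compares monozygotic (MZ) pairs, who share all
their segregating genes, with dizygotic (DZ) pairs, who share half on
average. For a standardized phenotype, the ACE model writes the within-twin
variance and cross-twin covariance as

    Var(y)            = a² + c² + e²  = 1
    Cov(y₁, y₂ | MZ)  = a² + c²
    Cov(y₁, y₂ | DZ)  = ½·a² + c²

with additive-genetic (A), shared-environment (C) and nonshared-environment
(E) components. Multivariate extensions build p × p component matrices
**A**, **C**, **E** and model the 2p × 2p twin-pair covariance with
within-twin block **A** + **C** + **E** and cross-twin block
r·**A** + **C** (r = 1 for MZ, ½ for DZ):

* **Common pathway** — a single latent factor, itself decomposed into
  A/C/E, drives all tests through loadings λᵢ; each test's residual carries
  its own A/C/E. **A** = a_F²·λλᵀ + diag(a_sᵢ²), and likewise for C and E.
* **Hierarchical** — a second-order general factor loads (γ_k) on
  first-order factors, which load (λᵢ) on tests; genetic variance enters at
  all three levels.
* **Cholesky** — lower-triangular path matrices **L**_A, **L**_E over
  ordered phenotypes apportion each trait's genetic variance into the part
  explained by traits entered earlier (e.g., general cognitive ability *g*)
  and the part unique to it.

All models are fitted by maximizing the multivariate-normal likelihood of
each pair's observed scores (FIML, so missing data are handled per
pattern), and the share of a trait's genetic variance captured by a common
factor is obtained by path tracing:
`(common_a² · λ²) / (common_a² · λ² + specific_a²)`.

## Worked example

Simulate a realistic five-group cohort (1,330 pairs) whose six tests share
a common factor that is 64% heritable, then decompose one test and the
common factor:

```r
library(twinpath)

design <- cohort_design(178, 169, 325, 260, 398, seed = 2024)
gen <- common_pathway_gen(variance_components(0.64, 0.08, 0.28),
                          loadings = c(0.54, 0.58, 0.63, 0.67, 0.71, 0.75),
                          specific_ace = variance_components(0.20, 0.05, 0.75),
                          phenotypes = c("sc", "pt", "nd", "rm", "mr", "nl"))
cohort <- simulate_common_pathway_cohort(design, gen)

icc <- intraclass_correlations(cohort, "nl")
cat(sprintf("rMZ = %.2f, rDZ = %.2f\n", icc$rMZ, icc$rDZ))
uni <- fit_univariate_ace(cohort, "nl")
confint(uni)
cp  <- fit_common_pathway(cohort)
```

Printed output:

```
rMZ = 0.46, rDZ = 0.32
ACE model for 'nl' (FIML over MZ 347, DZ 983 pairs)
  standardized components: a2 = 0.287, c2 = 0.178, e2 = 0.535
  -2lnL = 7391.607, AIC = 7399.607, npar = 4
   2.5 % 97.5 %
a2 0.096  0.466
c2 0.047  0.309
e2 0.463  0.617
Common pathway model (ACE), 6 indicators
  common factor: a2 = 0.579, c2 = 0.096, e2 = 0.325
  standardized loadings: sc 0.52, pt 0.59, nd 0.62, rm 0.68, mr 0.69, nl 0.75
  -2lnL = 40219.702, AIC = 40283.702, npar = 32
```

Reading the numbers: the MZ pairs are noticeably more alike than DZ pairs
(`rMZ = 0.46` vs `rDZ = 0.32`), so the single-test decomposition attributes
29% of variance to additive genetics with a wide profile-likelihood
interval — exactly what ~1,300 pairs can resolve for one test. Pooling the
six tests through the common pathway model sharpens the picture: the latent
factor behind all tests is estimated 58% heritable (generating value 64%),
with loadings recovered at their generating 0.54–0.75 values. The
per-indicator `cp$genetic_shares` then reports how much of each test's
genetic variance the common factor captures.

A complete simulate → preprocess → CFA → twin-models run, driven by a
YAML/JSON config with a mandatory seed, is available through
`run_pipeline()` (or `inst/scripts/run_pipeline.R` from a shell); it writes
a cohort CSV, descriptive and model-comparison tables, twin-model JSON, a
plain-text report and a run manifest.

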