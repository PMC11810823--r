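---
title: "Comparing mixed models for feather-score evaluation in half-sib cage tests"
author: "rtblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing mixed models for feather-score evaluation in half-sib cage tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtblup)
```

## The problem

Feather damage in laying hens is scored as a three-level categorical trait
(10 = intact plumage, 15 = damaged feathers, 20 = bald patches) on the back
and neck at 45 and 70 weeks of age. In recurrent progeny tests, the
daughters of one sire are housed together in cages; all cage mates share
the sire and have unknown dams from a single dam line, so they are
(approximately) paternal half-sibs with identical pedigree information.
Two consequences shape everything in this package:

* because cage mates are sibs, an ordinary linear mixed model applied to
  these records estimates *total* breeding values — the sum of an
  individual's direct genetic effect on its own plumage and its social
  (pecking) effect on cage mates. Direct and social effects are not
  separable in this design, but their sum is exactly what selection needs;
* survival and feather score are genetically correlated, and birds that die
  before scoring have no feather record, so univariate analyses of feather
  score are exposed to selection bias.

`rtblup` implements the full comparison cycle for six candidate models:
data simulation, pedigree-based REML/BLUP fitting, and cage-masked
cross-validation of estimated sire effects.

## The six models

All models share one fixed-effect structure: the recurrent-test batch
number (`rt_number`), a combined farm-by-housing-date-by-cross factor
(`fdc`, one level per unique triple), and the fast-feathering gene
genotype. They differ in data level, genetic parameterization and trait
set:

| name  | level      | genetic | traits        | random cage | residual cov |
|-------|------------|---------|---------------|-------------|--------------|
| IBAM  | individual | animal  | FS + survival | yes         | fixed at 0   |
| IUAM  | individual | animal  | FS            | yes         | —            |
| CUAM  | cage       | animal  | FS            | no          | —            |
| IBSiM | individual | sire    | FS + survival | yes         | free         |
| CBSiM | cage       | sire    | FS + survival | no          | free         |
| CUSiM | cage       | sire    | FS            | no          | —            |

Cage-level records are the mean score of the survivors and the fraction of
the original cage alive at scoring. CUAM assigns the cage record to one
random member of the cage, testing whether an animal-model
parameterization adds anything over a sire model (it does not: the two give
correlations above 0.99 between sire rankings, with animal-model EBVs
exactly twice the transmitting abilities).

In IBAM the residual covariance between feather score and survival is
fixed at zero: every bird with a feather record has the same survival code
(alive), so the data contain no information about that covariance. Sire
models keep 3/4 of the additive variance inside the residual, which leaves
enough variation to estimate the covariance freely.

## Synthetic data generator

No individual-level records of this design are publicly available, so the
generator is a first-class component, calibrated to reference
descriptives of large commercial recurrent tests (on the order of 10^5
hens in ~12,600 cages from ~2,100 sires):

* **Design.** Each sire has daughters in `m = 6` cages with `n = 53`
  daughters in total from `d = 20` unidentified dams. Cage sizes are
  `3 + Binomial(19, p)` with `p` chosen so the mean size is `53/6 = 8.83`,
  matching both the reported range (3–22) and the reported totals. A
  sire-line pedigree of configurable depth (default 4 generations) makes
  the test sires realistically related; daughters enter the pedigree with
  unknown dams.
* **Liability model.** Feather score is generated by cutting a Gaussian
  liability (sire transmitting ability + cage effect + residual, total
  variance 1) at two thresholds per trait. The reference data report only
  trait means (11.32 / 12.42 / 13.98 / 14.78), not category frequencies, so
  the split between the two damaged categories follows a fixed policy,
  P(15) = 4·P(20); thresholds are then solved so the expected mean equals
  the target. Because the cage-level fixed effects (batch, farm-date-cross,
  feathering gene) add between-group variance, the cutpoints are
  recalibrated against the realized fixed-effect offsets, keeping the
  realized means on target.
* **Variance components** (liability scale, defaults):
  `sigma2_S = 0.042`, `sigma2_c = 0.15`, `sigma2_e = 0.808`. Dams are
  never identified, so dam and Mendelian-sampling variation (3/4 of
  `sigma2_A = 4 sigma2_S`) are absorbed into the residual, exactly as in
  the real design. The sire variance was chosen so that the cage-level
  expected-accuracy formula, evaluated on fitted observed-scale
  components, gives ≈ 0.62 for the default design — the accuracy level the
  comparison is designed to operate at. (Thresholding attenuates the sire
  signal relative to noise: a liability-scale choice of the same ratio
  would understate the intended observed-scale accuracy.)
* **Survival** is cumulative (dead at 45 weeks implies dead at 70) with
  marginal rates 98% and 94%, simulated from its own liability that shares
  sire genetics with feather score (genetic correlation 0.4, within the
  0.2–0.6 range sire models estimate on such data; sire variance 0.02,
  reflecting that additive variance for survival is near zero). Dead birds
  have missing scores at that age. Survival carries no cage effect or
  fixed effects; its calibration is therefore exact by construction.
* **What is not emulated:** egg-production traits, explicit dam-line
  structure, occasional full-sib cage mates, within-cage pecking dynamics,
  and real-data pathologies (mis-scoring, pedigree errors). Passing tests
  therefore demonstrate correctness of the estimation and validation
  machinery under the design's assumptions, not robustness to real-data
  artifacts.

The raw records of the emulated scheme give per-cage score *counts*, not
bird-level scores; `make_individual_dataset()` implements the standard
reconstruction argument — allocating counts to random surviving cage
members is fully equivalent for genetic analysis because all cage members
share the same pedigree.

## REML engine

`reml_fit()` assembles Henderson's mixed-model equations sparsely
(`Matrix`): the genetic block is augmented by `A^-1 ⊗ G0^-1` with the
pedigree-based `A^-1` built directly by Henderson's rules from
Meuwissen–Luo inbreeding coefficients, the cage block by `C0^-1 ⊗ I`, and
records missing one trait (dead birds' scores) simply contribute no
equation for that trait, so bivariate models keep the survival record of
every bird.

Variance components maximize the restricted log-likelihood
`-2 lR = log|R| + log|G| + log|C| + y'Py + const`, evaluated per candidate
through one sparse Cholesky factorization of the coefficient matrix. The
search is a quasi-Newton iteration (`nlminb`) over log-Cholesky-transformed
covariance blocks, which keeps every 2×2 block positive definite by
construction; for univariate models the residual variance is profiled out
analytically, leaving a 1–2 parameter search. This direct-maximization
design was preferred over average-information updates because it is simple,
has no step-rejection machinery, and at the problem sizes used here (up to
~25k equations) each likelihood evaluation is well under a second.

Numerical choices worth knowing:

* traits are standardized to unit variance internally (survival codes have
  ~20× smaller scale than scores); estimates are reported back-transformed,
  and the likelihood includes the exact Jacobian on the contrast space;
* fixed-effect blocks are reduced to full column rank per trait by pivoted
  QR; aliased levels (e.g. batch nested inside farm-date-cross) are dropped
  and counted in `fit$aliased`;
* variance parameters are bounded on the log scale (ratios in
  `[1e-8, 1e8]`); estimates at the bound set `fit$boundary`, and
  non-convergence within `maxit` flags `fit$converged = FALSE` rather than
  erroring — flat likelihoods in the survival covariance parameters are
  the typical cause;
* the restricted log-likelihood was verified against a dense textbook
  oracle (`V = ZGZ' + R`) including the bivariate missing-record case, and
  REML equals the ANOVA estimator on balanced one-way designs to machine
  precision of the convergence tolerance.

## Validation design

`cross_validate()` implements 10-fold cross-validation that masks *cages*:
fold assignment depends only on the cage list and seed, so training sets
are identical across models. For each fold and model the training fit
yields estimated sire effects `s_hat` (animal-model EBVs are halved onto
the transmitting-ability scale); these are compared against the masked
cages' pre-corrected phenotypes `Ybar_obs` — cage-average residuals of a
fixed-effects-only model on the complete data.

* **Accuracy** = EMMEAN over folds of `r(s_hat, Ybar_obs)` divided by the
  EMMEAN of `r(s1, Ybar_obs)`, the correlation between *true* sire effects
  and proxies implied by the variance components:
  `r(s1,Ybar) = sqrt[ (sA2/4) / (sA2/4 + sc2 + (3/4 sA2 + se2)/n_bar) ]`
  with `n_bar` the realized mean cage size. The components default to the
  individual-level bivariate animal model's per-fold estimates
  (`vc_source = "IBAM"`); `vc_source = "fit"` reuses each model's own
  components (for cage-level sire models the same quantity is
  `sqrt(sS2/(sS2+se2))`). The choice rescales all models identically and
  cannot affect their comparison, so the cheaper option is used wherever
  only one model is validated.
* **Dispersion** is the OLS slope of `Ybar_obs` on `s_hat`; correctly
  dispersed BLUP has expectation 1, slopes below 1 flag over-dispersion.
* **T²** = `sigma2_A / sigma2_P` (animal models) or `4 sigma2_S / sigma2_P`
  (sire models), the total-heritable-variance analogue of heritability.
  Cage-level phenotypic variances are smaller because dam, Mendelian
  sampling and residual parts average over cage members, so cage-level T²
  runs higher — a property of the record type, not a disagreement between
  models.
* **Expected accuracy** per model family follows the reliability of a
  progeny test with `d` dams, `n` daughters and `m` cages per sire; e.g.
  `R2 = sS2/(sS2 + se2/m)` for cage-level sire models.

Per-fold metrics are compared across models with fold as a blocking factor
(`value ~ model + fold`), using `emmeans` marginal means, Tukey-adjusted
pairwise contrasts, and a compact letter display computed by the
insert-and-absorb algorithm (implemented here; models sharing a letter do
not differ at α = 0.05). Dispersion means are additionally tested against
1. Accuracy EMMEANs are computed on raw correlations, not Fisher-z — at
these correlation levels (≈0.2 per fold) the transformation changes
nothing visible and raw values keep the accuracy ratio interpretable.

Two estimator properties observed while validating the implementation are
worth recording. First, with related test sires the realized variance of
true sire effects sits below the base-population `sigma2_S`; fitted
components reflect the realized quantity, so the correction stays
consistent. Second, at the scaled-down study size (200 sires) the accuracy
estimator targets the *training* accuracy of masked sires (which keep ~5
of their 6 cages), slightly below the full-data accuracy; both converge at
the real study's scale. The per-trait estimate carries a Monte-Carlo
standard deviation of about 0.07 at 200 sires, which is why summary
statements use the mean across the four feather-score traits (sd ≈ 0.02).

## Problem sizes and defaults

Default analyses run at 200 test sires (~10,600 birds, 1,200 cages), where
a cage-level REML fit takes well under a second and a full 10-fold
validation a few seconds on one core; individual-level bivariate fits
(~25k equations, 8–9 covariance parameters) are the expensive corner at a
few minutes. The test-suite experiments use 20-replicate batches at 100–150
sires, and generator-calibration checks use ~50,000 birds, chosen so each
check resolves its target within Monte-Carlo error.

## Known limitations

* The observed scale is linear: no threshold (probit) model is fitted, so
  estimated components refer to scores, not liabilities — deliberately
  matching the practice the package evaluates. Observed-scale genetic
  variances are larger for the 70-week traits simply because their means
  are more intermediate.
* Direct and social genetic effects are not separable in this design; all
  genetic quantities are totals.
* The category-split policy (P(15) = 4·P(20)) is an assumption; only the
  trait means are pinned by the reference descriptives.
* `IBSiM`/`IBAM` likelihoods are nearly flat in the survival covariance
  parameters when mortality is low; expect boundary or non-convergence
  flags there, with stable feather-score components regardless.
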