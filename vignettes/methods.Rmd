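---
title: "Gene-binned multiple imputation for RNA-seq differential expression: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-binned multiple imputation for RNA-seq differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`mivoom` estimates per-gene associations between bulk RNA-seq expression
and an ordinal exposure — a count of prenatal stressful life events (SLE,
0–14) or of maternal childhood traumatic events (CTE, 0–3) — adjusted for
confounders, precision variables, and optionally potential mediators, in
the realistic situation where covariate values are partially missing.
Exposure and expression are never imputed: samples missing the exposure
are dropped at the start of every analysis.

This vignette documents the statistical machinery, the synthetic-cohort
generator that validates it, the numerical choices, and the design
decisions that were genuinely open.

## The differential-expression core

Counts are filtered to protein-coding genes, processed pseudogenes and
lncRNAs, and to genes whose average smoothed log2-CPM across the analysis
samples is at least 0 (a mean of exactly 0 is retained; the filter removes
strictly negative means). Filtering is applied separately per analytic
sample set, because the SLE and CTE analyses keep different samples.
Library sizes are normalised by the weighted trimmed mean of M-values
(trim 0.3 on log-ratios, 0.05 on abundance, upper-quartile reference),
computed by edgeR behind the package's `tmm_factors()` surface and
cross-checked in the tests against an independent step-by-step
implementation of the estimator.

Smoothed log-CPM is `log2((count + 0.5) / (libsize * factor + 1) * 1e6)`.
The pseudo-count of 0.5 (and 1 = 2 × 0.5 on the library size) is a
standard smoothing convention; note it makes the "doubling counts and
depths changes nothing" identity exact only in the large-count limit,
which is how the tests state it. Whether filtering precedes normalisation
is not dictated by the method; this package filters first and computes
factors on the retained genes, recording both choices in configuration.

Per gene, a linear model is fitted by weighted least squares with
observation-level precision weights interpolated from the mean–variance
trend (voom; smoother span 0.5), and residual variances are moderated by
empirical Bayes: the prior `(d0, s0^2)` is estimated by moment matching of
the log residual variances to a scaled-F model, and the posterior variance
is `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`. `ebayes_moderate()` exposes the
two limits explicitly — `prior_df = 0` reproduces the ordinary t-test,
`prior_df = Inf` pools all genes — and the default moment estimate is
cross-checked against the reference empirical-Bayes implementation in the
tests. FDR control is Benjamini–Hochberg across all tested genes, with
significance reported at 0.05 and additionally counted at 0.10. Effects
are log2 fold-changes per one-unit exposure increase, also reported as
percent change `(2^log2FC − 1) × 100`.

## Missing covariates

Three strategies share this core:

**Gene-binned multiple imputation (primary).** Genes are randomly
partitioned into bins (default 50 genes). Within a bin, incomplete
covariates are imputed `M` times (default 10) by chained equations whose
predictors are all other covariates, the exposure, and the log-CPM of the
bin's genes — including the outcome in the imputation model is what makes
the imputation congenial with the analysis and is the reason for binning:
all ~14,000 genes at once would be a predictor matrix wider than the
cohort. Continuous variables use predictive-mean matching with 5 donors
and proper Bayesian draws of the regression parameters; binary variables
use a logistic posterior draw; categorical variables (>2 levels) draw the
category from class posteriors of a regularised linear discriminant on
the same predictors (a multinomial-logistic engine is available behind a
flag; the discriminant is an order of magnitude faster at equal
imputation fidelity in our checks, though neither draws the category-model
parameters, which slightly understates between-imputation variance for
those variables). A model that fails (e.g. separation) falls back to
marginal draws. Default 10 sweeps of the chained equations; the variables
are visited in order of increasing missingness.

Per imputed dataset the design matrix is rebuilt, precision weights are
re-estimated, all genes are refitted, and variances are moderated across
all genes *within that imputed dataset*; the moderated variances then
enter Rubin's rules ("moderate before pooling"). The alternative — pool
raw variances, squeeze the pooled variances once — is available as
`moderation = "after_pooling"`. The total variance is
`T = Ubar + (1 + 1/M) B` and the reference df follow Barnard–Rubin with
`nu_com` taken as the average moderated total df across imputations. When
the imputations agree exactly (`B = 0`, no missing information) the df is
set to `nu_com` so that a zero-missingness run reduces *exactly* to the
direct pipeline; the tests assert gene-by-gene agreement to 1e-8 on the
t-statistics. Per-bin imputation seeds are `seed + bin index`, so results
do not depend on execution order.

**Random-forest single imputation.** An iterative scheme: initialise with
marginal means/modes, then refit each incomplete variable as a random
forest on the other covariates plus the exposure, looping until the
summed out-of-bag error increases (max 10 passes).

**Complete case.** Drop any sample missing a design value.

The three are compared by the Spearman correlation of per-gene p-value
ranks; on the desk-scale synthetic cohort MI and single imputation agree
above 0.9.

## The synthetic cohort

The generator emulates the cohort the method was built for, with
marginals frozen to the published sample descriptives: maternal age
truncated-normal 27.884 (5.677) on [16, 43] (the underlying parameters
are re-solved from closed-form truncated moments so the *truncated*
moments match); BMI and income truncated-lognormal; gravidity truncated
Poisson; neighborhood deprivation truncated normal; race/ethnicity/
education/household-size/labor-type/delivery frequencies as published;
tobacco 7.7%, alcohol 9.4%. Study site uses the sequenced-subset split
(73/27) and sequencing batch is three equal batches; gestational age
(38.8 ± 2.2 weeks) is included so the sensitivity design variant can be
exercised — these three are not in the published table and are the
package's own choices.

Exposures: the SLE sum follows a zero-inflated negative binomial
truncated to 0–14 with (pi = 0.149, mu = 1.854, size = 1.982), solved
once so that mean = 1.576, SD = 1.861 *and* P(0) = 0.379 — the zero mass
implied by the published exposure quadrant; a plain truncated NB matching
mean and SD alone misses the zero mass and inflates the both-exposed
fraction. The three CTE items are correlated Bernoullis (rates 26.3%, 8%,
19%) driven by one shared standard-normal factor with item loading
0.7352, solved so that P(CTE = 0) = 0.637; the SLE latent loads 0.358 on
the same factor, solved against the published Spearman correlation 0.226.
With one latent factor the rank correlation and the joint quadrant cannot
be tuned independently; the frozen loading reproduces rho ≈ 0.226 and a
both-exposed fraction of ~26.7% against the published 26.1%. Higher-order
dependence is unconstrained by the published statistics and is whatever
the copula implies.

Counts are negative binomial with expected value
`mu_gs = CPM_g/1e6 * L_s * 2^(beta_g * exposure_s)`, lognormal library
sizes (default mean 1e6 — a desk-scale depth; the real study sequenced
~30M reads — with sigma 0.15), baseline abundances lognormal and pinned
at 50 CPM for the designated effect genes so they survive filtering, and
a decreasing mean–dispersion trend `phi_g = 0.04 + 3 / mean count`
(asymptotic BCV 0.2). The default planted effects are the three published
per-event log2 fold-changes +0.07, −0.04, −0.03.

Missingness defaults to the published per-variable rates (exposure 17.9%,
CTE 3.4%, income 5.3%, ...; the three CTE items and their sum are masked
jointly). MCAR masks uniformly. MAR ties the missingness odds of every
masked variable to supplied fully-observed scores through a logistic
model whose intercept is re-solved per variable so the marginal rate
still matches. The packaged MAR scenario drives missingness with the
expression of the effect genes plus the exposure — the outcome-dependent
mechanism that biases complete-case analysis and that outcome-including
imputation exists to fix; missingness depending only on fully-observed
covariates would leave complete case unbiased for regression coefficients
and make the comparison uninformative. MNAR is out of scope.

What the generator does *not* emulate: count overdispersion beyond a
smooth mean–dispersion trend, batch effects on expression, correlated
gene modules (genes are conditionally independent given the exposure),
gene length variation, or item-level SLE structure. Passing tests
therefore demonstrate the estimator's statistical properties under the
assumed sampling model, not robustness to every feature of real cohort
data.

## Enrichment ensemble

Five base tests per gene set (sets restricted to the tested universe,
sizes 10–500): hypergeometric over-representation of the top-500 genes by
raw p (a fixed-size list rather than an FDR-gated one, because an
analysis with zero FDR-significant genes must still produce a ranked
enrichment, as the CTE analysis structure requires); a competitive
correlation-adjusted mean test on z-scaled moderated t-statistics with
variance inflation `1 + (m − 1) rho` (default rho 0.01); z-score and
leading-singular-vector sample scores regressed on the exposure within
the full design (the singular-vector sign is fixed by positive
correlation with mean member expression); and a Welch location test of
member versus non-member statistics. Method p-values are combined by the
twice-the-average rule, `min(1, 2 * mean(p))`, BH-adjusted within the
collection, and directed by the unweighted mean member log2FC.

The combination rule deserves its own paragraph, because the obvious
candidates fail a property this pipeline needs. The five base tests are
positively correlated — several are different functionals of the same
gene statistics. Fisher's chi-square reference assumes independence and
on fully null simulations produced spuriously small combined p-values
(about 7.5% of null sets below 0.05, minima near 1e-5, enough for BH to
flag sets). Wilkinson's minimum-p rule is conservative overall under
positive dependence, but a single method's extreme tail passes straight
through the minimum, and with thousands of null sets scanned over many
seeds, one method's slight deep-tail inflation (the singular-vector test
runs about 1.4x nominal at p = 0.01) periodically yields an FDR-significant
null set. More fundamentally, any *calibrated* combined p-value gives BH
a ~5% chance per analysis of at least one false set under a global null
(Simes equality), so stable "no false sets" behaviour requires deliberate
deep-tail conservatism. The twice-the-average rule is a valid p-value
under arbitrary dependence, reaches small values only when the methods
agree, and still ranks coordinately perturbed sets first because a real
signal moves every method; both classical rules remain available via
`rule =`. The rotation/permutation family of set
tests is deliberately not implemented; the ensemble machinery is
method-count agnostic and a three-to-five method subset reproduces the
ensemble's behaviour. Sex-stratified runs drop fetal sex from the design
and add a male/female direction-concordance table. No curated gene-set
collections are bundled; GMT files are read from disk and synthetic
collections can be generated for calibration studies.

## Numerical choices and degenerate inputs

* Categorical reference levels: most frequent level. Exposure inference
  is invariant to this choice.
* Rank-deficient designs are an error naming the aliased columns, never a
  silent drop — except the deliberate removal of fetal sex in
  within-stratum designs.
* `fitFDist` may return `d0 = Inf` (all variances equal); the moderation
  arithmetic handles it by using the prior variance everywhere.
* In Rubin pooling, `lambda = 0` (B = 0) short-circuits to
  `nu = nu_com`; p-values use the t distribution on possibly fractional
  df.
* Combined p-values clamp zeros to 1e-300 with a warning; skipped
  (NA) methods reduce `k`.
* The voom trend is clamped to its endpoints outside the fitted range.
* TMM reference selection ignores all-zero genes, making the factors
  invariant to padding the matrix with unexpressed genes.

## Problem sizes

The validation suite runs at desk scale, chosen once as the package's
test conditions: the reduction-identity fixture is 2,000 genes × 600
samples with M = 5; null-calibration runs use 20 seeds of 2,000 genes ×
200 samples with M = 2, bin 100, 2 sweeps; effect-recovery runs simulate
the full published cohort size (n = 1,065, so ~875 samples carry the
exposure) over 8 seeds each for the MCAR-recovery and MAR-comparison
studies, at 300 genes; the concordance check uses the 2,000 × 600 fixture
with M = 3. The full published scale (14,047 genes, 30M reads) remains
configurable (`scale = "full"` in `run_config()`).

## Known limitations

* The categorical imputation engine does not draw its class-model
  parameters, mildly understating between-imputation variance for
  categorical covariates.
* `nu_com` under moderation-before-pooling is an average across
  imputations; no exact finite-sample theory covers moderated-then-pooled
  variances.
* The ensemble's combined p-value is used for ranking; its null
  behaviour under the default Wilkinson rule is verified empirically (no
  q < 0.05 sets on null data in the acceptance suite), not analytically.
* Complete-case bias under MAR depends on the missingness mechanism; the
  packaged scenario (outcome-driven missingness) is one point in that
  space, chosen because it is the case the method targets.
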