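---
title: "Estimating and modelling species-level cancer mortality risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and modelling species-level cancer mortality risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

comparonc estimates how often adult mammals in managed (zoo) populations
die of cancer, species by species, and asks whether that risk scales with
body mass and adult life expectancy across the mammalian tree — the
comparative question usually framed as Peto's paradox. This vignette is
the package's account of the statistical machinery: the estimators, their
conventions, the tunable parameters, and the synthetic worlds used to
verify the chain end to end.

## From individual records to adult cohorts

The unit of raw data is one animal: species, sex, birth date (with a
precision in days), death date or alive-at-extraction status, necropsy
availability, and a cause category (`cancer`, `other`, `unknown`).
`filter_eligible()` applies the study-design rules:

* a fixed observation window (default 2010-01-01 to 2020-05-30);
  individuals dead before the window never enter;
* birth dates known to at most 30 days, because age is the dominant
  cancer covariate and sloppier records would blur it;
* adulthood only: an individual enters at its age at sexual maturity
  (sex-specific; for unsexed animals the *maximum* of the male and female
  maturity ages, so no juvenile can slip in), or at its age on the window
  start date if it was already adult then — this is left truncation, and
  every survival quantity downstream uses delayed-entry risk sets;
* survivors at extraction are right-censored at their age that day.

Ages are exact day differences divided by 365.25. Dead animals without a
necropsy stay in the cohort — they carry survival information — but their
cause is `unknown`, which matters for the complete-case incidence below.
Species enter the analysis only with at least 20 necropsied adults
(`apply_species_thresholds()`; 40/60/80/100 form the usual sensitivity
ladder), and domesticated species are excluded
(`exclude_domesticated()`; the packaged list is a generic set of common
domesticates, not a reproduction of any particular curated list).

## Survival with delayed entry

`km_fit()` is a product-limit estimator in which an individual is at risk
at event age *t* iff `entry < t <= exit`. Two conventions are fixed and
tested rather than left to chance:

* deaths at *t* precede censorings at *t* (the standard tie rule), and
* the risk-set condition is strict on the left, so an individual dying at
  its own entry age does not remove itself from the numerator's risk set.

With all entries at zero this reduces exactly to the classical
Kaplan–Meier (the suite checks equality against an exact-fraction
textbook oracle and against `survival::survfit`). Adult life expectancy
is the area under the survival step function from maturity to the last
observed age — a *restricted* mean, flagged `truncated` whenever the
curve does not reach zero; we deliberately do not extrapolate beyond the
data. `survival_quantile()` reports the first event age at which survival
drops to a level *q*; species whose curves never reach 10% are excluded
from the incidence analysis, since their old-age survival is not
identified.

## Two risk metrics: CMR and ICM

CMR is the crude ratio of cancer deaths to necropsied individuals. It
ignores censoring and truncation, which is why the package also computes
the cumulative incidence of cancer mortality:

ICM = Σₓ Sₓ hₓᶜ, summed from maturity onward,

with Sₓ the all-known-cause survival on the *complete-case* set (known
cause deaths plus censored survivors; unknown-cause deaths are dropped,
assuming cause-missingness is random) and hₓᶜ = dₓᶜ/nₓ the cancer-specific
hazard jump from a product-limit pass in which only cancer deaths are
events. Hazard mass is carried at exact event ages — not pooled over
calendar intervals — because species differ enormously in event spacing,
and S enters as its **left limit** at each jump. The left-limit convention
is not cosmetic: it is the unique choice under which the cause-specific
incidences and the terminal survival add to one *exactly* on fully
observed cohorts (the suite proves this in rational arithmetic on random
cohorts; a `s_convention = "right"` switch exposes the alternative for
comparison). On complete uncensored data ICM collapses to the crude
cancer fraction, which is both a sanity check and the reason CMR and ICM
correlate strongly on realistic data.

ICM is *undefined* — not zero — when the complete-case set is empty or
the 10%-survival rule fails; downstream models receive missing values.

## The phylogenetic engine

All comparative models sit on one GLS core (`gls_fit()`): error
covariance σ²·D C(λ) D, where C(λ) is the shared-path-length matrix with
off-diagonals scaled by Pagel's λ and D = diag(1/√w) turns case weights
into precision multipliers (a species weighted twice behaves exactly like
a duplicated row — tested algebraically). Solving is Cholesky-based;
singular designs are a hard error naming the collinear columns, because a
pseudo-inverse would silently hide data problems. λ is profiled by ML on
[0, 1] (`lambda_ml()`, tolerance 1e-6, explicit endpoint checks); ML
rather than REML so likelihood-ratio comparisons between nested λ values
are valid, and an optimizer drifting below zero is pinned to λ = 0, the
conventional refit rule. `phylo_signal()` is the intercept-only special
case with a χ²(1) LR test (an optional boundary correction halves the P
value; off by default, matching common practice).

The detection side of the risk distribution is binary, so
`binary_pglmm()` fits a logistic regression with a phylogenetically
structured random effect b ~ N(0, s²C) by penalized quasi-likelihood:
working-response linearization with the working restricted likelihood
maximized over s² at each sweep. With s² = 0 it collapses to ordinary
IRLS (tested against `glm`), and its estimates track the standard PQL
reference implementation. PQL standard errors are first-order
approximations; the parameter-recovery suite quantifies the resulting
small-sample optimism rather than pretending it away.

## The zero-inflated two-part model

Because many species show zero observed cancer deaths, risk is modelled
in two parts (`fit_zero_inflated()`):

1. **Detection** — phylogenetic logistic regression of "any cancer death
   observed?" on log necropsy count (more necropsies, more chances to see
   one case), log body mass and log adult life expectancy.
2. **Magnitude** — λ-profiled PGLS of logit(risk) on log body mass and
   log adult life expectancy, on strictly positive species only, weighted
   by the natural log of the necropsy count (the base is a convention the
   data do not pin down; it is exposed through the weights argument).
   Restricting the logit to the positive part is the whole point of the
   two-part design: no zero-correction constant is ever needed.

Covariates enter on the natural-log scale; per-doubling effects are a
reporting-layer rescaling by log 2. An interaction term and a
high-leverage exclusion list are options, off by default. `predict_risk()`
inverts the magnitude part to percentages; `partial_r2()` compares nested
fits by prediction error, where each species' prediction is its
conditional expectation given all other species under the fitted
covariance (so the phylogeny participates in the prediction, not only in
the fit), clipped at zero.

Sex bias is tested by `phylo_paired_ttest()`: an intercept-only GLS on
within-species differences under C(λ̂). On a star tree the t statistic is
exactly the classical paired t. Degrees of freedom default to n − 2,
charging one df for the estimated λ; published analyses differ by ±1 here,
so the `df` argument makes the convention explicit. Diet effects are
per-food-item PGLS fits on the recoded binary flags
(never/occasional → 0, secondary/primary → 1), and order differences are
deliberately *non*-phylogenetic one-way linear models on percentage risk
with Tukey-adjusted pairwise contrasts via emmeans — order membership and
phylogeny are confounded by construction, so these are descriptive.

## Synthetic worlds and what passing tests mean

`simulate_world()` generates the whole data structure with known truth:
a unit-depth pure-birth tree; ln mass and ln adult life expectancy by
Brownian motion; per-species cancer-death probability
p = logit⁻¹(β₀ + β_m·ln m + β_l·ln e + u) with u ~ N(0, σ²C(λ)); then
individual records — calendar birth dates independent of lifetimes (so
left truncation is non-informative by construction), exponential or
Gompertz adult mortality, right-censoring at extraction, MCAR necropsy
missingness, and a pinch of imprecise birth dates and pre-window deaths
so every eligibility rule is exercised. One master seed fans out to named
substreams (tree, traits, lifetimes, necropsy), making each stage
independently reproducible.

Default magnitudes, chosen once and stated here so they are not mistaken
for estimates: 150 species × 300 records; β₀ = −2.8 (≈6% baseline risk);
β_mass = −0.15 and β_lifespan = +0.8 per natural-log unit — the
*directions* seen in real zoo mammals, with magnitudes set by an a-priori
identifiability analysis so that the default design recovers the signs
reliably (chance correlation between a λ-structured residual field and
Brownian covariates makes weaker slopes unidentifiable at n = 150);
λ = 0.8, between the signals reported for the two risk metrics in real
data; residual SD 1.0 on the logit scale, matching the very wide spread
of real species risks; necropsy probability 0.9, which at 300 records per
species yields 60–80 necropsied adults, the real database's per-species
average. The `near_null` preset carries the real point effects
(−2.9%/doubling mass, +25%/doubling life expectancy) for sensitivity
work, and `strong` exaggerates both for power demonstrations.

What the synthetic worlds do *not* emulate: species-correlated necropsy
effort (an MNAR stress variant is a one-line change of
`necropsy_prob` handling left to the user), age-dependent cancer fraction
within species, measurement error in literature life-history covariates,
and multi-tree phylogenetic uncertainty. Passing the recovery suite
therefore shows the chain is internally consistent under its own
assumptions — not that those assumptions hold for any particular real
extract.

Known numerical and inferential limitations, measured rather than hidden:
per-species binomial sampling noise attenuates λ̂ (the recovery criterion
budgets ±0.25 for this); PQL confidence intervals are mildly optimistic
at small n (coverage checked at the 85% level); and the paired t-test,
while exact on star trees and correctly sized under the
shared-species-effect null, becomes anticonservative if the *differences*
themselves are strongly phylogenetically correlated at n ≈ 36 — a regime
its users should treat with caution.

Problem sizes used by the automated checks — chosen as the package's
standard verification conditions — are: exact-fraction oracles on all
cohort patterns up to 6 members (several hundred cases), 100 random
cohorts for the additivity identity, 10,000-member exponential cohorts
(20 replicates) for the life-expectancy closed form, 20 default worlds
for parameter recovery, and 1,000 replicates per tree for the paired-test
calibration.
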