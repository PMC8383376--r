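---
title: "Measuring socioeconomic inequity in maternal and child health indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring socioeconomic inequity in maternal and child health indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the procedure

Household surveys of maternal and child health (MCH) record binary outcome
indicators (teenage pregnancy, under-five mortality, stunting, ...) and
coverage indicators (skilled prenatal care, facility delivery,
immunization, ...) together with household asset ownership.  The question
this package answers is *how unequally* each indicator is distributed across
the socioeconomic gradient, in three steps:

1. **Identify** the health outcome or intervention whose distribution is to
   be measured.
2. **Stratify** the population by an equity stratifier — here an asset-based
   household wealth index, plus urban/rural residence and maternal
   education.
3. **Measure** the degree of inequality — with concentration curves and
   concentration indices over the full wealth gradient, and with
   richest-versus-poorest risk ratios at the extremes.

```{r, eval = FALSE}
library(mchequity)
survey <- generate_survey(sim_config(n_households = 10000, seed = 2026))
wi     <- build_wealth_index(survey$households)
et     <- build_equity_table(survey, wealth_index = wi)
print(et)
```

## The wealth index

Each binary asset indicator is standardized to mean 0, standard deviation 1
(population convention, denominator *N* — immaterial to ranks, fixed for
bit-reproducibility).  The index weights are the loadings of the **first
principal component** of the standardized asset matrix: the single linear
combination capturing the largest share of common variation in asset
ownership.  A household's score is the loading-weighted sum of its
standardized assets, re-standardized to mean 0, sd 1.

Choices worth stating explicitly:

* **Orientation.** An eigenvector is defined up to sign; the sign is chosen
  so scores correlate nonnegatively with the household's total asset count
  (more assets ⇒ richer).
* **Unweighted PCA.** The component is fitted over all sampled households
  without design weights; design weights enter only the ranking and the
  quantile cutpoints.  A weighted-PCA switch would be easy to add, but the
  unweighted fit is the convention for asset indices and is the default.
* **A single index for the whole sample** — urban and rural subsamples are
  never fitted separately, so scores are comparable across residence.
* **Constant asset columns** (everyone or no one owns the item) carry no
  ranking information; they are dropped with a warning rather than failing,
  because field data routinely contain saturated assets.
* **Ties** in score (identical asset profiles) are broken by ascending
  household id, everywhere, so every downstream artifact is deterministic.

Households are then ranked by score and cut into weighted quintiles and
deciles: walking households poorest to richest, a household is assigned the
group containing the midpoint of its own weight interval,
`ceiling(k * (cumweight - w/2) / W)`.  Every group's total weight is within
one household's weight of `W/k`, and a household heavier than a whole group
lands in the single group holding its midpoint.  Label 1 is the poorest
group, `k` the richest; deciles nest in quintiles (`decile ∈ {2q-1, 2q}`).

## The concentration curve and index

Order individuals poorest to richest by their household's score.  The
concentration curve `L_h(p)` is the cumulative share of the health variable
held by the poorest fraction `p` of the (weighted) population; it lies above
the diagonal when the variable is concentrated among the poor.  The
concentration index is

* **curve form**: `C = 1 − 2 ∫ L_h(p) dp`, integrated by the trapezoid rule
  over the piecewise-linear curve;
* **discrete form** (equal weights): `C = (2/(N·μ)) Σ h_i r_i − 1 − 1/N`
  with ranks `r_i = i/N`;
* **covariance form**: `C = (2/μ) cov_w(h, r)`, the weighted population
  covariance (total-weight denominator) between the variable and the
  fractional rank.

`C` is bounded in [−1, 1]; negative values mean concentration among the
poorer (pro-poor), positive among the richer (pro-rich), zero an equal
distribution.

**Rank convention.** The default fractional rank is the *endpoint*
convention `r_i = (Σ_{j≤i} w_j)/W`, which reduces to `i/N` for equal
weights — under it the discrete and covariance forms are *algebraically
identical*, which the test suite verifies to machine precision.  The common
*midpoint* convention `(cumweight − w_i/2)/W` is available behind a flag; it
does not reduce to `i/N` on small samples, but it makes the index exactly
antisymmetric under rank reversal for arbitrary weights (the endpoint form
is exactly antisymmetric only under equal weights, with a discrepancy
bounded by `w_i/W` otherwise).  The curve form differs from the covariance
form by at most `1/N` (trapezoid discretization).

**Numerical tie-outs.** A constant health variable returns exactly 0 (the
covariance with any rank is identically zero; the implementation
short-circuits this case so no floating-point residue leaks through).  A
zero-mean variable has no defined index and raises an error; in the equity
table such a row is emitted with its index cells marked undefined and the
pipeline continues.

**Binary indicators** are analyzed with the plain index.  For a binary
variable with mean μ the plain index is bounded by ±(1−μ), so comparisons
across indicators with very different prevalence conflate inequality with
prevalence; the Wagstaff (`C/(1−μ)`) and Erreygers (`4μC`) normalizations
address this but change the quantity being reported, so they are offered
only as explicit post-corrections and never applied by default.

## Standard errors and significance

Published equity tables star their indices without stating a variance
formula, so the variance machinery here is the package's own choice:

* **Analytic (default).** A delta-method (influence-function) variance for
  `C = 2T/μ̂` that accounts for the estimated mean:
  `φ_i = (2/μ)[(h_i−μ)(r_i−r̄) − T] − (C/μ)(h_i−μ)`,
  `Var(Ĉ) = Σ (w_i/W)² φ_i²`.  With equal weights this coincides with the
  heteroskedasticity-robust slope SE of the "convenient regression" of
  `2σ_r² h_i/μ` on `r_i`, whose slope is exactly `Ĉ`.  The acceptance suite
  checks its calibration directly: under a null generator (no
  wealth–outcome association) the rejection rate at α = 0.05 over 1,000
  simulated surveys of 5,000 households must lie in [0.03, 0.07].  The
  analytic path refuses samples below N = 30.
* **Bootstrap.** Units are resampled with replacement (keeping their
  weights), re-ordered by the original wealth ordering, ranks recomputed,
  and the index recomputed; seed-controlled, B = 1000 by default.

Both give two-sided normal p-values.  Stars follow the standard ladder
(`*` p < 0.1, `**` p < 0.05, `***` p < 0.01), and the direction label is
"equal" whenever p ≥ 0.1 regardless of sign.

**These p-values are design-naive.** The variance treats units as
independently weighted draws; multi-stage cluster sampling of real surveys
would inflate variances (design effects), so real-data stars would be
somewhat too generous.  The equity table carries a note to this effect.

## Risk ratios

The richest-versus-poorest comparison uses only the top and bottom wealth
groups: RR(quintile 5 : quintile 1) and RR(decile 10 : decile 1), plus
RR(urban : rural) and RR(higher : lower education) — numerator always the
first-listed group.  Each RR is a ratio of design-weighted prevalences; its
95% interval and p-value use the **Katz log-normal method** with effective
sample sizes `(Σw)²/Σw²` standing in for counts under unequal weights.  A
zero count that blocks the log-RR variance triggers a 0.5 continuity
correction (flagged in the result); a zero *denominator prevalence* yields
an infinite-RR sentinel with a warning rather than an error.  No
multiple-testing correction is applied across indicator rows.

## What the synthetic generator emulates — and what it does not

Real MCH survey microdata are typically restricted, so the package ships a
generator whose structure matches what the analysis assumes, with known
ground truth:

* **Latent wealth** `w ~ N(0,1)` per household; **assets** owned with
  probability `plogis(γ_j w + c_j)`, conditionally independent given wealth
  (a one-factor model — the minimal structure under which a first principal
  component is the right index).  Defaults: 10 assets, loadings `γ_j`
  uniform on [0.8, 2.0] per SD of wealth, intercepts uniform on
  [−1.25, 1.25].  Those loadings describe strongly wealth-graded durables
  (electricity, television, refrigerator, vehicle); pilot simulation at
  these defaults shows the fitted index recovers the latent ranking with
  Spearman ρ ≈ 0.88 at 10,000 households, comfortably above the 0.8
  recovery threshold the tests assert.
* **Strata and weights.** Three default strata (urban 35%, southern rural
  45%, northern rural 20%) with the northern stratum oversampled
  (sampling fraction 1.6 vs 0.9) — the design is deliberately not
  self-weighting, as national surveys that oversample small regions are
  not.  A sampled household's design weight is `share/fraction` for its
  stratum, normalized to mean 1 (the scale cancels in every weighted
  estimator).
* **Indicators** are Bernoulli with logit
  `α + β w + residence_effect·urban + education_effect·higher`; education is
  itself Bernoulli with logit depending on wealth and residence.  `β` is
  the ground-truth inequity dial: `β = 0` forces the population index to 0,
  and `calibrate_effect()` bisects on `β` (with common random numbers
  across bisection steps, so the objective is deterministic and monotone)
  until the mean *estimated* index over R replicate pipelines hits a target
  such as −0.133 within ±0.01.
* **Seeding.** One global seed; every stage (strata, wealth, each asset,
  education, each indicator) draws from its own deterministically derived
  substream, so identical configs give byte-identical fixtures and adding
  an indicator never perturbs earlier draws.

Not emulated: multi-stage cluster sampling (and hence design effects on
variances), item nonresponse, correlated assets beyond the single factor,
household-size variation in indicator denominators (a
`records_per_household` knob stands in for the woman/birth/child
denominator, which real indicators define per indicator).  Passing tests
therefore demonstrate the *estimators* are correct under the assumed
sampling model, not that real-survey standard errors are correctly sized.

## Problem sizes used by the checks

The test suite and the reproduction script run at desk scale, chosen so the
Monte-Carlo error of each check is small relative to its tolerance: formula
identities on 1,000 random series of up to 1,000 units; calibration recovery
at 10,000 households per survey (a baseline-prevalence-0.5 indicator, whose
single-survey index SE ≈ 0.006, so the ±0.02 recovery band is about three
Monte-Carlo SEs); type-I error over 1,000 surveys of 5,000 households;
direction-consistency over 50 random surveys of 1,500 households.

## Known limitations

* Design-naive variances (see above); no cluster bootstrap.
* The plain index for binary variables depends on prevalence bounds;
  normalizations are opt-in.
* No decomposition of the index into determinants, no dominance tests
  between curves, no slope/relative indices of inequality.
* The generator's education model and effect sizes are stylized; they are
  dials for testing estimators, not demographic forecasts.
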