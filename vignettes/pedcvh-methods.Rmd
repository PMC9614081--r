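---
title: "Methods: pediatric cardiovascular health scoring, trends and attributable risk"
author: "pedcvh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pediatric cardiovascular health scoring, trends and attributable risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedcvh)
```

## The construct

`pedcvh` implements the seven-metric cardiovascular-health (CVH) construct
for children and adolescents, in the modified form used for Chinese
pediatric populations: four health behaviors (smoking, body-mass index,
physical activity, diet) and three health factors (blood pressure, total
cholesterol, fasting glucose), each graded **poor / intermediate / ideal**.
The composite CVH score counts metrics at the ideal level (0–7); scores
6–7 define ideal CVH, 3–5 intermediate, 0–2 poor.  A behavior score of 3–4
defines "ideal CVH behaviors" and a factor score of 3 "ideal CVH factors".

The grading rules, as implemented:

| Metric | Poor | Intermediate | Ideal |
|---|---|---|---|
| Smoking | tried in past 30 d | — | never tried |
| BMI | > 95th pct | 85th–95th pct | < 85th pct |
| Physical activity | 0 min/d | (0, 60) min/d | ≥ 60 min/d MVPA |
| Diet | 0–1 components | 2–3 | 4–5 |
| Blood pressure | > 95th pct | 90–95th pct, or SBP ≥ 120 / DBP ≥ 80 mmHg | < 90th pct |
| Total cholesterol | ≥ 200 mg/dL | [170, 200) | < 170 mg/dL |
| Fasting glucose | ≥ 126 mg/dL | [100, 126) | < 100 mg/dL |

The five diet components are fruits/vegetables ≥ 1/day, aquatic foods
≥ 1/week, fried or western fast food ≤ 1/week (*inclusive*),
sugar-sweetened beverages < 1/week (*strict*), and bean-curd or dairy
≥ 1/day.

**Boundary semantics.** Published band labels are printed on an integer
grid ("170–199", "100–125"); real-valued laboratory results need gapless
intervals, so the intermediate bands are implemented half-open —
`[170, 200)` and `[100, 126)` — which preserves the printed poor
thresholds (≥ 200, ≥ 126) exactly.  For the percentile metrics the ideal
band is strictly below the lower cut (`< p85`, `< p90`), values exactly at
a cut fall in the intermediate band, and poor requires strictly above p95.
Zero MVPA minutes map to poor; any positive amount below 60 min/d is
intermediate.  Smoking has no intermediate level.  These choices are
locked by an exhaustive boundary test suite and an independently written
brute-force classifier that must agree with the vectorized implementation
on 10,000 randomized records.

## Reference model

BMI-for-age and height-for-age references use the LMS system: a Box-Cox
power `L`, median `M` and coefficient of variation `S` per sex on an age
grid, giving `z = ((x/M)^L − 1)/(L·S)` (the log form when `L = 0`).
Percentile cut-offs invert this transform at the standard-normal quantile.
`L`, `M`, `S` are interpolated linearly in age between grid points, which
is how such references are published; requests outside the grid are a hard
error, because silent extrapolation would corrupt classification.

Blood-pressure references are a complete sex × integer-age × height-band
grid of SBP/DBP 90th/95th percentiles.  The child's height is converted to
a height percentile via the height LMS reference and mapped to one of six
bands (default edges P5, P25, P50, P75, P95); bands are half-open and
closed on the left, so a percentile exactly at an edge belongs to the
upper band — a deterministic, documented tie rule.  Age is truncated to
completed years.  Whether published BP standards use height bands or
continuous height percentiles varies; the banded lookup was chosen as the
common published layout, and the band edges are configurable.

The national reference publications themselves are external, so the
package ships **synthetic** reference tables
(`inst/extdata/synthetic_*.tsv`, rebuilt by `synthetic_reference_set()`):
smooth logistic-in-age median curves with plausible `L` and `S` values,
and a BP grid whose cells are the 90th/95th quantiles of normal
distributions with means linear in age and band.  They make the package
buildable and testable offline and are clearly labelled; user-supplied
tables in the documented TSV layout replace them for real analyses.

## Synthetic cohort generator

Because the survey data the analysis design comes from are not deposited,
the generator is a first-class module: it draws three cross-sectional
waves (2004, 2014, 2019) with the statistical structure the downstream
stages assume.

Two standard-normal latent factors per child induce realistic
correlations: an **adiposity** factor loading on the BMI z-score (0.8),
fat-mass percentage (0.7), blood pressure (via the BMI coupling
`beta_bmi = 0.35` on the z scale) and mildly on TC/FBG (0.2); and a
**healthy-lifestyle** factor loading on the five diet components (0.45),
MVPA (0.5) and sedentary time (−0.3).  The magnitudes are stated
assumptions — the emulated surveys report directions, not correlation
magnitudes — chosen so that association analyses have signal to detect.

Marginals are calibrated so that, wherever the model admits a closed form,
the preset's implied prevalence is exact: BMI ideal status is
`pnorm(z85 − mu)` per sex; MVPA uses a lifestyle-linked uniform copula
through a zero-inflated log-normal whose `meanlog` is solved from the
target P(≥ 60 min); sedentary time likewise; TC is log-normal and FBG
normal with wave-specific moments; diet-component count distributions are
computed by Gaussian quadrature over the shared latent.  Blood pressure
and sleep adequacy interact with absolute thresholds (120/80 mmHg; the
age-dependent sleep bands), so `target_marginals()` evaluates those by
seeded Monte Carlo.  Wave presets encode the emulated period's pattern:
ideal BMI and BP decline monotonically across waves, activity/diet/TC/FBG
dip in 2014 and partially recover in 2019, smoking stays nearly
universally ideal, and girls fare better than boys on smoking, BMI and BP
but worse on activity.  The presets are *qualitative*: they reproduce
orderings and approximate levels, not the original estimates, and no
preset output should be mistaken for a reproduction of any study.

Ages are Beta-distributed on [6, 18] with concentration 2 (uniform at the
default mean of 12), allowing wave-specific mean-age shifts.  Covariate
missingness is MAR by construction: each of the 13 adjustment covariates
is blanked independently with a probability depending only on the
always-observed sex and wave (base rate 0.029, ×1.2 for boys), giving
roughly a third of records at least one missing covariate; the seven
metric inputs are never blanked.  Ground truth (latents and pre-blanking
covariates) is retained for recovery tests.

What the generator does **not** emulate: school-level clustering and
design weights, device/laboratory differences between waves (beyond
per-wave fat-mass moments), non-normal tails in anthropometry, item-level
questionnaire structure (MVPA arrives as minutes/day directly), and
missingness that depends on unobserved values (MNAR).  Passing tests
therefore demonstrate correctness of the statistical machinery under a
known MAR data-generating process, not robustness to survey artifacts.

## Trend statistics

Proportions carry Wilson score intervals (the interval method behind the
reported prevalences is rarely stated in survey reports; Wilson has good
small-sample behavior and is the default, with Clopper–Pearson as an
option).  The Cochran–Armitage trend test is implemented from its
definition with group scores 1..k in survey order (calendar-year scores
are an option; with three roughly equally informative waves the choice is
a scaling of the score vector).  Its two-sided p-value uses the normal
approximation; the test suite compares it against an exhaustive
conditional permutation oracle on small tables and checks its type-I
error at n = 300/group over 2,000 null simulations.  The exact
permutation p is discrete and conservative, so agreement within 0.02 is
asserted on tables with pronounced (or exactly null) trends, where the
approximation is inside the discreteness granularity.  Descriptive tables
use one-way ANOVA for continuous characteristics and Pearson chi-squared
without continuity correction (configurable) for categorical ones.

## Association models and attributable fractions

Ideal-CVH correlates are modeled by multivariable logistic regression via
IRLS (`stats::glm`, deviance tolerance 1e−8) with Wald CIs on the
odds-ratio scale — Wald rather than profile likelihood to match standard
epidemiological reporting.  Rank-deficient designs error naming the
aliased columns; suspected separation (non-convergence or |β| > 15) is a
flagged error rather than a silently unstable estimate.  The default
predictor set: sex, age group, household income, parental education and
weight status, parental CVD history, passive smoking, sedentary time,
sleep adequacy, prematurity, sexual maturity, fat-mass tertile and survey
wave.  Fat-mass tertiles are computed within survey wave because body
composition is measured by different devices across waves; pooling would
change what a tertile means.

The population attributable fraction of overweight/obesity (BMI status
not ideal) for each CVH factor uses **model standardization** as the
primary estimator: AF = 1 − mean(predicted risk with exposure at
reference) / observed case fraction, with a seeded nonparametric
bootstrap CI (bootstrap rather than the delta method because it is
directly verifiable against resampling truth; the method difference is
documented).  Levin's and Miettinen's closed forms ship as validation
oracles only — in the unadjusted binary-exposure case model
standardization reduces algebraically to Miettinen's estimator, and the
tests assert that identity to 1e−10.

## Multiple imputation

`impute_chained()` is a chained-equations imputer: variables with missing
values are visited in order of increasing missingness, each regressed on
all others over `maxit` sweeps (default 10, monitored by logged chain
means rather than a formal diagnostic), repeated for `m` datasets
(default 30, matching common practice for ~30% covariate missingness).
Conditional models by type: Bayesian linear regression for continuous
variables (scaled-inverse-chi-squared variance draw, normal coefficient
draw, then normal predictive draws; predictive mean matching with five
donors as an option), logistic for binary, multinomial for categorical,
each with an approximate posterior draw of the coefficients.  The
parameter perturbation is essential: deterministic regression imputation
would collapse the between-imputation variance to zero and understate
uncertainty.  Downstream estimates are combined by Rubin's rules
(`pool_rubin()`): Q̄ the mean, B the sample variance of estimates,
T = W̄ + (1 + 1/m)B, small-sample degrees of freedom
ν = (m−1)(1 + W̄/((1+1/m)B))², t-based intervals; B = 0 yields infinite
degrees of freedom.  Complete-case fits are produced alongside as the
sensitivity analysis.

## Numerical choices and degenerate inputs

* Latent z-scores are clipped to ±4 before the Box-Cox back-transform,
  which is undefined beyond z = −1/(L·S) for negative `L`; the clip
  affects ~6e−5 of draws and no calibrated marginal at test precision.
* DBP is capped at SBP − 5 mmHg to maintain the physiological ordering.
* Generated measurements are rounded to instrument-realistic precision
  (0.1 cm/kg/mmHg/mg-dL, whole minutes — floored so the 60-minute
  threshold is preserved exactly).
* Degenerate trend tables (all successes or all failures) return p = 1
  with a `degenerate` flag instead of dividing by zero.
* Fat-mass tertile breaks that tie (constant FMP) collapse to fewer
  bands rather than erroring.
* All randomness is seed-controlled: `generate_cohort(spec, seed)` is
  byte-reproducible, imputation and bootstraps take explicit seeds, and
  the pipeline driver derives stage seeds from one master seed.

## Problem sizes

The test suite exercises the oracle comparisons at 10,000 randomized
records (scoring), 2,000 null simulations (trend-test size), 500
simulations at n = 5,000 (logistic coverage), 50 replications at
n = 3,000 with 20% MAR and m = 5 (imputation coverage), and preset
recovery at n = 5,000 per wave.  The acceptance script generates the
three waves at their full emulated sizes (18,739 / 1,725 / 12,122) for
prevalence and trend quantities, and runs the imputation/association
stage on a 6,000 / 1,000 / 4,000 subsample with m = 5, maxit = 5 and 100
bootstrap resamples per attributable-fraction cell — sizes chosen to keep
a complete run in the low minutes while leaving every estimate's Monte
Carlo error well inside the reported precision.

## Known limitations

* The synthetic reference tables are plausible but not any published
  national standard; classifications against them are internally
  consistent, not externally comparable.
* Survey-design features (clustering, weights) are out of scope; all
  estimators are crude/unweighted, as in the emulated reports.
* The imputation engine handles the package's covariate types; it is not
  a general replacement for a full MICE implementation (no multilevel
  models, no passive imputation, no imputation of the metric inputs —
  records missing a metric are excluded by design).
* PAR confidence intervals are bootstrap percentile intervals; with few
  cases per stratum they can be wide and, in tiny strata, undefined.
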