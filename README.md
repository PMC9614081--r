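# pedcvh

Cardiovascular health (CVH) scoring, trend analysis and attributable-risk
modeling for children and adolescents.

Cardiovascular disease risk is shaped early in life, and pediatric
surveillance increasingly summarizes it with the American Heart
Association's CVH construct: four health behaviors — smoking, body-mass
index (BMI), physical activity, diet — and three health factors — blood
pressure (BP), total cholesterol (TC), fasting glucose (FBG) — each graded
**poor / intermediate / ideal**.  `pedcvh` is for epidemiologists and
biostatisticians who need that construct, in its modified pediatric form
with Chinese-style reference percentiles, as tested, reusable code:
scoring against growth/BP reference standards, composite scores, survey
trend statistics, logistic association models with multiple imputation,
and population attributable fractions.

## The model

Each metric is graded per the pediatric thresholds (Table-style summary in
`vignettes/pedcvh-methods.Rmd`): BMI against sex/age-specific 85th/95th
percentiles from an LMS reference (z = ((x/M)^L − 1)/(L·S)); BP against
age/sex/height-specific 90th/95th percentiles plus the absolute
120/80 mmHg rule; TC at 170/200 mg/dL; FBG at 100/126 mg/dL; activity at
60 min/d of moderate-to-vigorous exercise; diet as the count of five
healthy components; smoking as tried/never in the past 30 days.

The **CVH score** is the number of ideal metrics (0–7):

* ideal CVH: score 6–7; intermediate: 3–5; poor: 0–2
* ideal CVH behaviors: behavior score (smoking, BMI, activity, diet) 3–4
* ideal CVH factors: factor score (BP, TC, FBG) = 3

Around the score sit the analysis stages: Wilson intervals for prevalence,
the Cochran–Armitage test for trends across survey waves, multivariable
logistic regression for ideal-CVH correlates (pooled over multiply imputed
covariates by Rubin's rules), and model-standardized population
attributable fractions (PAR) of overweight/obesity for each CVH factor,
with Levin's and Miettinen's closed forms as validation oracles.

Because the survey data this analysis design targets are not publicly
deposited, the package includes a calibrated synthetic three-wave cohort
generator (`wave_presets()`, 2004/2014/2019) and synthetic reference
tables, so the entire pipeline is testable end to end; the presets
reproduce the *pattern* of the emulated period (a U-shaped dip in ideal
CVH in 2014, steadily worsening BMI and BP, sex disparities), not any
study's estimates.

## Worked example

```r
library(pedcvh)

refs    <- synthetic_reference_set()                       # LMS + BP grids
cohort  <- generate_cohort(wave_presets()[["2019"]], seed = 7, n = 2000)
profiles <- cvh_profile(cohort$participants, refs)

table(profiles$cvh_category)
#>         poor intermediate        ideal
#>          145         1529          326

prevalence_ci(sum(profiles$cvh_category == "ideal"), nrow(profiles))
#> proportion 16.3%, 95% CI 14.7-18.0   (Wilson interval)

waves <- generate_waves(n_per_wave = 2000, seed = 7)       # all three waves
prof  <- cvh_profile(waves$participants, refs)
trend_test(prof$cvh_category == "ideal", prof$survey_year)
#> Cochran-Armitage trend test: Z = -8.752 , two-sided p = < 2.2e-16

round(tapply(prof$cvh_score, prof$survey_year, mean), 2)
#> 2004 2014 2019
#> 4.85 3.56 4.30
```

The 2019 preset yields ~16% ideal CVH; across waves the mean score dips
from 4.85 (2004) to 3.56 (2014) and recovers to 4.30 (2019), and the
trend test flags the (negative, U-shaped) secular change.  The negative Z
reflects scores 1..3 on the survey order with the 2014 trough.

The full pipeline — simulate, score, publication-shaped report tables,
MI + association + PAR — runs with one master seed:

```r
run_pipeline("out/", seed = 1, n_per_wave = 3000, m = 5, maxit = 5)
```

or from a shell via the thin CLI:

```sh
Rscript inst/cli/pedcvh.R all --seed 1 --output out/ --n-per-wave 3000
```

## Layout

* `R/reference.R` — LMS machinery, BP grid, TSV loaders, synthetic tables
* `R/scoring.R`, `R/covariates.R` — metric grading, composite scores, derived covariates
* `R/cohort.R` — cohort specs, wave presets, generator, MAR missingness
* `R/trend.R` — Wilson/Clopper–Pearson intervals, Cochran–Armitage, descriptive tables
* `R/impute.R` — chained-equation MI, Rubin pooling
* `R/association.R` — logistic fits, PAR estimators, pooled suites
* `R/pipeline.R` — simulate/score/report/associate drivers, manifests
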