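Package: pedcvh
Title: Pediatric Cardiovascular Health Metrics, Trends and Attributable Risk
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for scoring cardiovascular health (CVH) in children and
    adolescents with the seven-metric modified American Heart Association
    construct (smoking, body-mass index, physical activity, diet, blood
    pressure, total cholesterol, fasting glucose), each graded
    poor/intermediate/ideal against pediatric reference percentiles.
    Includes LMS growth-reference and age/sex/height-banded blood-pressure
    lookups, composite CVH/behavior/factor scores, survey-trend statistics
    (Wilson intervals, Cochran-Armitage trend test), multivariable logistic
    association models, model-standardized population attributable
    fractions, multiple imputation by chained equations with Rubin pooling,
    and a calibrated multi-wave synthetic cohort generator for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
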