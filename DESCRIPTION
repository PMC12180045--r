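Package: planetdiet
Title: Planetary Health Diet Index Scoring and Cardiovascular-Kidney-Metabolic Disease Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Planetary Health Diet Index (PHDI), a 0-140
    diet-quality score built from 14 food-group components scored against
    EAT-Lancet reference intakes, including a bidirectional modification of
    the moderation components so that zero intake scores zero. Provides
    energy standardization to a common 2500 kcal/day basis, stratum-level
    aggregation with percentile uncertainty intervals, and component-wise
    decomposition of group differences. Classifies participants into
    cardiovascular-kidney-metabolic (CKM) syndrome stages 0-4 from
    metabolic disorder flags, the KDIGO kidney-risk grid, predicted
    10-year cardiovascular risk and clinical cardiovascular history, and
    classifies deaths from ICD-10 cause codes. Includes ecological
    analysis stages (linear time trends, sociodemographic index,
    restricted cubic splines, burden regression with Bonferroni
    adjustment), survey-weighted logistic and proportional-hazards models
    with design-based variance, and a synthetic-data module that generates
    stratified intake tables, burden tables and participant cohorts with
    known planted parameters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
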