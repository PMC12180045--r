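---
title: "Scoring the planetary health diet and staging CKM risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the planetary health diet and staging CKM risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planetdiet)
```

## The index

The Planetary Health Diet Index (PHDI) measures adherence to the
EAT-Lancet reference diet. Fourteen food groups are each scored 0–10 by
piecewise-linear ("proportional") interpolation against reference
intakes, and the component scores are summed, giving a total in
[0, 140]. Intakes are first standardized to a common 2500 kcal/day
energy basis, the basis on which the EAT-Lancet reference quantities are
defined. Two component units exist: grams/day (rescaled by
`target/basis` during standardization) and percent of energy
(basis-invariant by construction).

Three curve shapes cover all components:

* **adequacy** — score rises linearly from 0 at zero intake to 10 at the
  optimum and does not fall for higher intake (whole grains, whole
  fruits, nonstarchy vegetables, nuts/seeds, legumes, unsaturated oils);
* **unidirectional moderation** — 10 at zero intake, falling linearly to
  0 at the maximum reference (saturated oils/trans fats at 3.8% of
  energy, added sugars at 5% of energy);
* **bidirectional** — 0 at zero intake, rising to 10 at the optimum,
  then falling to 0 at the maximum reference (fish/shellfish, starchy
  vegetables, dairy, red/processed meat, poultry, eggs).

The bidirectional shape is the modification that motivates this
implementation: a purely downward moderation curve awards a perfect 10
to *zero* intake, which misreads undernourished populations as adhering
to a healthy diet. Under the modification, a profile of all-zero intakes
scores 20 rather than a large moderation windfall — only the two
remaining unidirectional components (saturated fats and added sugars)
keep their maximum at zero intake. `score_profile` on an all-zero
profile reproduces exactly that arithmetic.

Two variants ship: `full14` (all 14 groups, maximum 140) and `gdd13`,
which mirrors the Global Dietary Database situation — poultry intake is
unavailable, and nonsoy legumes and soy foods are only available as one
combined group — so 13 components and a maximum of 130. We read the
published 14-group list as already combining the legume sub-groups, so
the only set difference between the variants is poultry; the combined
legume group is shared.

### Reference values

The four anchors stated with the modified index are used verbatim: eggs
optimal at 13 g/day, red/processed meat zeroing at 28 g/day, saturated
oils/trans fats at 3.8% of energy and added sugars at 5% of energy. The
remaining optima are the EAT-Lancet 2500 kcal reference diet quantities
(whole grains 232 g, whole fruits 200 g, nonstarchy vegetables 300 g,
nuts/seeds 50 g, legumes 100 g, unsaturated oils 40 g, fish 28 g,
starchy vegetables 50 g, dairy 250 g, poultry 29 g). Upper references
for the bidirectional groups use the published EAT-Lancet upper ranges
where one is printed and twice the optimum otherwise (dairy 1000 g,
eggs 26 g, poultry 58 g, fish 100 g, starchy vegetables 200 g). These
defaults live in an editable YAML table
(`inst/extdata/phdi_full14.yaml`); the scoring engine and every test of
it are independent of the particular numbers, which users may replace
with their preferred citation via `load_scoring_config()`.

Open design points we resolved: "proportional" scoring is implemented as
linear interpolation, the convention in the published PHDI family;
adequacy components are not penalized above the optimum; each
bidirectional optimum can be a point or a plateau
(`optimal_low`/`optimal_high`), and the shipped defaults use points.

### Energy schedule

Stratified intake tables report on age-specific energy bases: 700
kcal/day under age 1, 1000 for 1 to <2, 1300 for 2–5, 1700 for 6–10,
2000 for 11–74 and 1700 from 75. `energy_basis_for_age_group()` parses
bracket labels ("0 to <1", "30-34", "95+") and applies the schedule at
the bracket midpoint, which deterministically resolves brackets that
straddle two standards (e.g. "5-9"); unparseable labels are errors, not
guesses. Aggregated stratum scores use the percentile (2.5th/97.5th)
uncertainty interval across estimation draws; some published stratum
intervals do not bracket their means, an aggregation convention we could
not reconstruct and deliberately do not emulate.

## CKM staging

Participants are classified into cardiovascular-kidney-metabolic (CKM)
syndrome stages 0–4:

| stage | trigger |
|---|---|
| 4 | clinical CVD history (heart failure, coronary artery disease, heart attack, stroke) |
| 3 | subclinical CVD: predicted 10-year CVD risk ≥ 20% or very-high KDIGO risk |
| 2 | diabetes, hypertension, hypertriglyceridemia, metabolic syndrome, or CKD (eGFR < 60 or albuminuria A2/A3) |
| 1 | overweight, abdominal obesity, or pre-diabetes |
| 0 | none |

Rules are evaluated top-down, so the assignment is total and monotone:
adding a disorder, raising kidney risk or raising predicted risk can
only raise the stage, and clinical CVD dominates every other input —
both properties are brute-force verified over the full discrete
criterion lattice in the test suite. Missing inputs propagate as an
*indeterminate* stage with the unknown fields named, never as a guessed
stage; an unknown lower-tier criterion cannot mask clinical CVD.

Metabolic thresholds (BMI ≥ 25; waist ≥ 102/88 cm by sex; fasting
glucose ≥ 126 mg/dL or HbA1c ≥ 6.5% for diabetes, 100–125 mg/dL or
5.7–6.4% for pre-diabetes; BP ≥ 130/80 mmHg or medication;
triglycerides ≥ 150 mg/dL; ≥ 3 of 5 ATP-III-style criteria for
metabolic syndrome, with the conventional 130/85 BP cut inside the
syndrome definition) are standard US clinical cut-points, held in
`study_config()` and overridable. The KDIGO kidney-risk grid is stored
as an explicit 18-cell table (6 eGFR bands × 3 albuminuria bands), and
the tests pin every cell at its band boundaries.

The 10-year CVD risk enters through a pluggable logistic interface
(`risk_model()`): the package deliberately does not derive or embed the
published PREVENT equation coefficients, which are consumed from a
user-supplied coefficient file; `risk_model_double()` is a clearly
synthetic stand-in used for pipeline exercise only. eGFR is likewise
consumed as an input rather than computed from creatinine.

CVD deaths are ICD-10 roots I00–I09, I11, I13 and I20–I51 ("deaths due
to heart diseases"); only the three-character root decides. I12 and the
cerebrovascular block I60–I69 are outside the definition, and the tests
check the complement exhaustively over the circulatory chapter.

## Ecological stages

`linear_trend()` is OLS of mean score on calendar year with a two-sided
slope test; the trend window is the set of years supplied by the caller
(source publications are inconsistent about 1990 vs 1999 start years, so
the window is an explicit input, not a constant). `sdi()` is the
geometric mean of pre-rescaled income, schooling and fertility indices —
the [0, 1] rescaling anchors belong to the data provider and are the
caller's declaration. `rcs_basis()` builds the restricted cubic spline
in Harrell's truncated-power form, 3 knots at the 10th/50th/90th
percentiles by default (k knots → k−1 columns; curve linear beyond the
boundary knots), for the SDI–PHDI dose-response.

`ecological_regression()` regresses log-transformed burden (burden
measures are positive and right-skewed; the transform is recorded in the
output and switchable to identity) on stratum score adjusted for year
(continuous), age group and sex (categorical), one fit per disease ×
measure, with Bonferroni adjustment over the number of diseases.
Rank-deficient designs error with the aliased terms named rather than
dropping them silently.

## Individual-level stages

`weighted_logistic()` fits the weighted logistic likelihood by IRLS
(`glm` with quasibinomial family) and computes design-based variance by
Taylor linearization: score contributions $w_i x_i (y_i - p_i)$ are
summed within PSU, and the stratified between-PSU covariance is
sandwiched between inverse weighted information matrices. Confidence
intervals and p-values use a t reference with (PSUs − strata) degrees of
freedom, the standard survey convention. Separation and single-class
outcomes are errors, never silent estimates. Effects are reported per 10
score points (continuous exposure), and the percentage risk reduction is
exactly $(1 - \mathrm{OR}) \times 100$.

`weighted_cox()` delegates to `survival::coxph` with case weights,
Efron tie handling (ties are common at coarse follow-up granularity) and
robust sandwich variance clustered on PSU; a stratum finite-population
correction is not applied, which is slightly conservative for typical
designs. Mortality models run among participants with the disease of
interest, with deaths classified all-cause or CVD via `is_cvd_death()`
and non-CVD deaths censored in the CVD models. `run_outcome_panel()`
assembles the forest-plot table across outcomes with Bonferroni
adjustment; the family size is a required analytical choice (defaulting
to the number of outcomes in the panel).

Complete-case analysis is the primary and only path; imputation-based
sensitivity analyses are out of scope. Replicate-weight variance methods
are not implemented.

## Synthetic data: what it emulates and what it does not

`synthetic_truth()` fixes every generating parameter: planted stratum
mean intakes (adult means on the 2000 kcal basis, scaled to each
stratum's energy basis), log-normal intake noise (intakes are
nonnegative and right-skewed; σ = 0.15 by default), a log-linear
ecological burden model with planted slope −0.02 per score point,
planted logistic log-odds per 10 points (default log 0.863, the scale of
the reported individual-level association), a planted log-hazard
(default log 0.85) with exponential event times and administrative
censoring at 240 months, variable log-normal survey weights, and a
two-PSU-per-stratum design — the simplest structure that exercises the
clustered variance code. Death causes are drawn from
{I21, I25, I50, I63} for a planted fraction (0.4) of deaths; I63 is
included on purpose because it is *not* in the heart-disease death
definition, keeping the classifier's exclusion under test. The log-normal
mean is bias-corrected (`meanlog = log(m) − σ²/2`) so draw means converge
to the planted means; a zero noise scale returns them exactly.

What the generator does **not** emulate: real-world marginal intake
distributions, correlation between food groups, informative weighting,
item nonresponse patterns, or calibrated biomarker joint distributions.
Passing parameter-recovery and coverage tests therefore demonstrates
that the estimators are correct under the stated sampling assumptions —
not that any substantive published estimate is reproduced, which would
require the original data sources.

Problem sizes used by the tests were chosen to make the statistical
assertions sharp at desk scale: parameter recovery at n = 20,000
(within 3 SE, and absolute log-OR bias below $2/\sqrt{n}$ per 10
points), null CI coverage over 200 replicates of n = 800 (95% ± 3%),
hazard-null coverage over 100 replicates of n = 600 (≥ 90%), ecological
null coverage over 500 replicates (95% ± 2%), 10⁵ random intakes for
boundedness and 10⁴ random component specs against an independently
coded dense-grid interpolation oracle at 10⁻¹².

## Numerical and degenerate-input conventions

Scores are clamped into [0, 10] after interpolation so floating-point
rounding cannot escape the range; an adequacy optimum of zero scores 10
everywhere (the limit of the rising segment). Noiseless regression
inputs are legal (the perfect-fit warning from `summary.lm` is
suppressed; a zero-variance slope yields p = 0 unless the slope is
itself zero). Aggregation of a single draw refuses to produce an
uncertainty interval. Country ranking breaks exact ties
lexicographically and flags them. CSV round-trips preserve integers
exactly and doubles to better than 10⁻¹² relative error
(17-significant-digit formatting). All generators are deterministic
given `synthetic_truth(seed)`; repeated calls are bit-identical.

## Known limitations

* The default component reference table is a documented editable
  convention, not a normative restatement of any single source; analyses
  intended for publication should load their citation's table.
* Stage prevalence in the presence of missing biomarkers is reported as
  indeterminate; no imputation is attempted.
* The ecological stage supports only year/age/sex adjustment, matching
  the data typically available at stratum level; it cannot support
  individual-level causal claims.
* Survey variance is first-order linearized; small numbers of PSUs per
  stratum (< 2) are rejected rather than approximated.
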