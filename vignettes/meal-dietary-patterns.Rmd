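---
title: "Methods: meal patterns, protein bolus and dietary patterns from food diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meal patterns, protein bolus and dietary patterns from food diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealtrace)
```

## The analysis in one paragraph

`mealtrace` takes a multi-day food diary — one row per consumed item with a
clock time on a 15-minute grid, a self-indicated meal label, a food-group
code, and precomputed weight (g), energy (kJ) and protein (g) — and a
participant table (sex, age, height, weight, education). After exclusion
filtering it derives, per participant: hourly intake profiles and eating
and drinking occasions (EDOs); protein by self-indicated meal with 30 g
bolus flags and a dinner-to-lunch surplus redistribution; protein adequacy
against 1.1 g/kg (adjusted) body weight; sex-stratified dietary patterns
from a varimax-rotated PCA of log food-group intakes; and Spearman and
logistic-regression associations among all of these.

## Stage-by-stage conventions

### Exclusions

Participants are excluded when height or weight is missing, when they
recorded no intake, or when mean daily energy over recorded days is
extreme: below 800 or above 4000 kcal/day (men), below 500 or above
3500 kcal/day (women). The inequalities are strict, so a woman at exactly
3500 kcal/day is retained. Energy is held in kJ internally and converted
at 4.184 kJ/kcal. The mean over recorded days (rather than any single
day) decides the band, so one feast day cannot exclude an otherwise
ordinary 4-day record. Each exclusion is logged with exactly one primary
reason, in the precedence order no-intake, missing anthropometry, extreme
energy.

### Hourly profiles and EDOs

Clock hour *h* collects the items recorded at (h−1):30, (h−1):45, h:00 and
h:15 — items at 6:30 through 7:15 count as intake "at 7 o'clock". Items at
23:30/23:45 wrap to hour 0 of the *same* recorded day: recording days are
treated as independent units, so no intake leaks across days. An hour is an
EDO when its energy strictly exceeds 210 kJ (210 kJ exactly is not an
EDO); an EDO holding at least 15 % of that day's energy (inclusive) is
large, otherwise small. Hours are the EDO unit; adjacent EDO hours are not
merged. EDO counts are summed per day and averaged over recorded days.

### Meals, bolus and redistribution

Protein is summed within each day by the participant's own meal label;
anything not named breakfast/lunch/dinner pools into "other". Day sums are
averaged over recorded days, a meal never reported contributing 0. Bolus
flags compare the across-day mean to 30 g (inclusive) — so a participant is
counted once per meal, which is the shape of a per-participant attainment
table; flagging individual days would answer a different question. The
meal-protein CV is the sample SD (n−1) over the three main-meal means
divided by their mean. The redistribution counterfactual moves
max(0, dinner − 30) g from dinner to lunch per participant, conserving
each person's total; lunch attainment can only rise and the operation is
idempotent. The lunch-by-dinner bolus association is a Pearson chi-square
on the 2×2 flag table, without continuity correction unless requested; a
zero margin flags the test as not computed.

### Anthropometry

For BMI > 25 kg/m² the adequacy denominator is
`25·height² + 0.25·(weight − 25·height²)`; the function is continuous at
BMI 25 and never lowers g/kg relative to observed weight. BMR uses the
Henry weight-and-height equations; the shipped coefficient CSV carries the
published 60+ bands for both sexes (the target population), errors outside
them, and is user-editable — whether the original analyses used Henry's
weight-only or weight-and-height form is not documented, so the
weight-and-height form was chosen because height enters the stated inputs,
and the choice is switchable via the table. PAL (reported energy / BMR) is
descriptive output only. Protein E% uses 17 kJ/g; the factor is an
argument because nutrient databases differ.

### Dietary patterns

The intake matrix is mean g/day per food group (25 groups; "other" and
"supplements" are excluded as a mixed bag and a low-consumer group).
Zeros are structural — most participants report no legumes or nuts at all —
so the log transform is ln(x+1), the smallest natural offset on the gram
scale, keeping non-consumption at exactly 0; the offset is an argument.
Columns are standardised to unit variance before eigendecomposition
(correlation PCA): gram scales differ by orders of magnitude across groups
(coffee vs fats/oils), and covariance PCA would load almost entirely on
beverages. Components with pre-rotation eigenvalue > 1.0 are varimax-
rotated (Kaiser row normalisation, tolerance 1e-8); those > 1.5 form the
analysis set. Thresholds apply to pre-rotation eigenvalues, read as
extraction criteria. After rotation, each component's largest-|loading|
entry is forced positive and components are re-ordered by explained
variance, making output invariant to linear-algebra backend sign and order
choices. Scores are standardised principal scores carried through the
orthogonal rotation — this avoids inverting the correlation matrix, so
small strata with fewer participants than food groups still score — and
are rescaled to unit SD. Tertiles of adherence are computed within sex;
with n not divisible by 3 the first `ceiling(n/3)` ranked observations form
tertile 1 (n = 10 → 4/3/3), ties break by stable input order, and an
all-equal degenerate stratum collapses to tertile 1 with a warning.

### Associations

Spearman correlations use average ranks for ties, pairwise-complete
observations and two-sided p-values from the t approximation; constant
variables are flagged rather than silently correlated. No multiplicity
correction is applied, matching the descriptive intent. The logistic suite
models the binary outcome "meets ≥ 1.1 g/kg" per sex:

* **daily block** — protein (per 5 g), energy (per MJ), total EDO (per 1),
  each adjusted for age (continuous) and education (two dummies, primary
  reference) only, then all three mutually adjusted in one model;
* **meal block** — protein at each meal (per 5 g) individually, and one
  additive model with all four meals; both always adjusted for age,
  education, energy and total EDO;
* **pattern block** — each retained score (per score SD) individually and
  jointly, same adjustment set.

The daily "individually adjusted" column is the only one without energy
and EDO in the adjustment set; since the exact set for the meal-block
individual models is ambiguous in prose descriptions of such designs, the
adjustment set is printed alongside every estimate. ORs carry Wald 95 %
CIs, exp(β̂ ± 1.96·SE). Perfect separation is flagged and the model
skipped; a constant outcome raises an error rather than a silent fit.

## The synthetic-cohort generator

The generator exists so the pipeline is testable with known truth, with
defaults calibrated to the scale of a national 4-day record survey of
60–80-year-olds. Per participant it draws sex (47 % male), age, height and
weight (sex-specific normals: men 68 ± 6 yr, 1.78 ± 0.07 m, 84 ± 12 kg;
women 68 ± 5 yr, 1.65 ± 0.06 m, 69 ± 11 kg), education
(22/45/33 %), and a small fraction (3 %) with missing height or weight to
exercise the exclusion stage. Per day it draws three main meals at
grid-snapped clock times (7:30, 12:30, 18:00 ± ~1 h) with lognormal
protein re-parameterised to the configured mean/SD — lognormal because
intakes are skewed and nonnegative (men 17.3/23.2/33.4 g at
breakfast/lunch/dinner, women 14.0/20.0/27.4 g, with their SDs) — plus
Poisson(1.7) snacks at distinct off-meal hours pooled under "other"
(per-snack mean scaled so the daily "other" total matches its configured
mean). Meal energy is protein × 17 kJ/g divided by a per-meal protein-E%
target (15 % breakfast, 19 % lunch/dinner, 13 % snacks, ~17 % daily) with
10 % multiplicative noise, so EDO thresholds are exercised at realistic
energies and daily totals land inside the exclusion bands. Snack rate and
meal-E% were chosen once so that total EDOs land near 4.7/day and daily
E% near 17 %.

Food-group item weights carry a planted low-rank structure *injected
before item assembly*: log-grams per group = baseline + 0.8·(Λ f) + noise
(SD 0.5), with participant factor scores f ~ N(0, I) and a sparse default
Λ (three factors: bread/potatoes/cheese; porridge/milk/cake; vegetables/
fruit, at 0.8 with 0.5 side-loadings). Each group's daily item lands at a
main meal drawn from a per-group meal-affinity table, and meal protein and
energy are split over the meal's items proportionally to weight. The
`truth` record returns the planted meal-protein parameters, Λ and factor
scores for recovery testing.

What the generator does *not* emulate: survey sampling strata and weights,
underreporting, seasonal and weekday effects, the item-level food
composition database, and — by default — within-person day-to-day
correlation of intake. No published value exists for that correlation, so
it is exposed as `day_corr` with default 0. A consequence worth knowing:
the configured meal-protein SDs are day-level SDs, so participant-level
across-day means have SD smaller by ~1/√n_days, and participant-level
bolus attainment rates in synthetic cohorts are correspondingly more
concentrated around the meal means than in a survey where stable
between-person differences dominate. Raising `day_corr` moves variance
from within- to between-person without changing the marginal moments.
Passing tests therefore demonstrate correctness of the pipeline's
arithmetic and recoverability of planted structure, not that any synthetic
cohort reproduces a particular survey's percentages.

## Problem sizes and numerical choices

The test suite runs cohorts of 500 participants (shared across test
files), 1000 × 2 days for moment-fidelity checks, 10 000 direct draws for
redistribution properties, 50 seeds of 500 × 25 noise matrices for the
eigenvalue-retention control, and 200 replicate fixtures of n = 500 for
CI coverage — sizes at which the checked tolerances (means within 1 g,
congruence > 0.9, coverage 91–99 %) have comfortable margins under the
fixed seeds. Varimax uses tolerance 1e-8 with Kaiser normalisation;
eigen-decomposition is the symmetric branch of LAPACK via `eigen()`;
protein conservation in the redistribution is exact up to floating-point
addition and asserted at 1e-9.

## Limitations

Energy and protein arrive precomputed per item; no nutrient calculation,
underreporting correction, survey weighting or causal interpretation is
attempted. The bolus threshold treats 30 g as a hard cutpoint regardless
of protein quality. Meal labels are taken as given, never inferred from
clock time. The Henry coefficient table ships only the 60+ bands; younger
cohorts require extending the CSV.
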