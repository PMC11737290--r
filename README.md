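# mealtrace

Protein intake in older adults is not just a daily total: muscle protein
synthesis responds to how much protein arrives *per meal*, and dietary advice
has to work with the meal and dietary patterns people already have.
`mealtrace` analyses time-stamped multi-day food diaries (one row per
consumed item, clock time on a 15-minute grid, self-indicated meal label,
food group, weight, energy, protein) and answers, for a cohort of older
adults:

- how intake distributes over the day, as **eating and drinking occasions
  (EDOs)** — clock hours with more than 210 kJ (~50 kcal) of intake, split
  into *large* (≥ 15 % of the day's energy) and *small*;
- which participants reach a **protein bolus of 30 g per meal** at
  breakfast, lunch, dinner or elsewhere, and what happens to lunch
  attainment if each person's dinner surplus (intake above 30 g) were
  **redistributed to lunch**;
- which **a-posteriori dietary patterns** emerge from a principal component
  analysis of log-transformed food-group intakes (g/day, 25 of 27 groups)
  with varimax rotation, retaining components by eigenvalue (> 1.0 for
  display, > 1.5 for analysis);
- how daily intake, meal-specific intake and pattern adherence associate
  with meeting a **protein adequacy target of ≥ 1.1 g per kg body weight**,
  via sex-stratified logistic regression.

For participants with BMI > 25 kg/m², the adequacy denominator is the
adjusted body weight

```
adjusted bw = bw@BMI25 + 0.25 · (bw − bw@BMI25),   bw@BMI25 = 25 · height²
```

and basal metabolic rate uses the published Henry weight-and-height
equations (MJ/day) for ages 60+. Exclusion filters drop participants with
missing height/weight or extreme mean energy intake (< 800 / > 4000
kcal/day in men, < 500 / > 3500 in women).

Because national survey microdata are not redistributable, the package
ships a seeded **synthetic-cohort generator** that emulates the survey's
statistical structure — three daily energy peaks, per-meal protein
means/SDs by sex, ≈ 4.7 EDOs/day, per-meal food-group mixtures, and a
planted low-rank food-group covariance — so every stage of the pipeline is
testable against known truth.

## Worked example

```r
library(mealtrace)
res <- run_pipeline(cohort_config(n_participants = 200, seed = 42))

100 * mean(res$frame$meets_cutoff)
#> 38.9   # % of retained participants at >= 1.1 g protein / kg adjusted bw

subset(res$bolus, meal %in% c("lunch", "dinner"),
       c(sex, meal, mean, sd, pct_attain, surplus_g_rounded))
#>      sex   meal mean   sd pct_attain surplus_g_rounded
#>   female  lunch 19.7 5.30       4.55                 2
#>   female dinner 27.0 5.10      25.45                 4
#>     male  lunch 23.6 5.67      12.50                 3
#>     male dinner 32.3 7.88      60.00                 7

res$redistribution$attainment
#>      sex pct_before pct_after
#>   female       4.55      7.27
#>     male      12.50     37.50
```

Reading: in this synthetic cohort 60 % of men reach the 30 g bolus at
dinner with a mean surplus of 7 g; moving each man's dinner surplus onto
lunch would triple male lunch attainment (12.5 % → 37.5 %). The logistic
suite (`res$tables$models`) reports odds ratios per reporting unit — e.g.
a 5 g/day higher protein intake carries OR ≈ 2.5 (95 % CI 1.7–3.6 in
women) for meeting the 1.1 g/kg target, adjusted for age and education.

`run_pipeline()` also accepts recorded data
(`list(diary = "diary.csv", participants = "participants.csv")`), writes
all table analogues, long-format hourly profiles and a run log to
`out_dir`, and echoes any threshold override. A thin command-line wrapper
lives at `inst/scripts/mealtrace.R`.

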