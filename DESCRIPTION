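Package: mealtrace
Title: Meal Patterns, Protein Bolus Attainment and Dietary Patterns from
    Time-Stamped Food Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyse time-stamped multi-day food diaries from older adults:
    detect eating and drinking occasions (EDOs) on an hourly grid, summarise
    protein by self-indicated meals, score 30 g protein-bolus attainment and
    a counterfactual surplus redistribution from dinner to lunch, derive
    a-posteriori dietary patterns by principal component analysis with
    varimax rotation, and model the odds of meeting a 1.1 g protein per kg
    adjusted body-weight target.  Includes a seeded synthetic-cohort
    generator emulating the statistical structure of a national 4-day
    dietary survey so the whole pipeline is testable without microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
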