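test_that("Spearman matrix has unit diagonal, symmetry and exact extremes", {
  f <- tibble::tibble(x = c(1, 2, 3), y = c(6, 5, 4), z = c(2, 9, 4))
  m <- spearman_matrix(f)
  expect_equal(unname(diag(m$rho)), rep(1, 3))
  expect_equal(m$rho, t(m$rho))
  expect_equal(m$rho["x", "y"], -1)
  expect_true(all(abs(m$rho) <= 1 + 1e-12))
})

test_that("Spearman agrees with the rank-then-Pearson oracle under ties", {
  set.seed(12)
  for (rep in 1:40) {
    n <- sample(5:25, 1)
    x <- sample(1:6, n, replace = TRUE) + round(runif(n), 1)  # many ties
    y <- sample(1:4, n, replace = TRUE)
    m <- spearman_matrix(tibble::tibble(x = x, y = y))
    expect_equal(m$rho["x", "y"], spearman_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("constant variables are flagged, not silently correlated", {
  f <- tibble::tibble(x = rnorm(10), k = rep(3, 10))
  m <- spearman_matrix(f)
  expect_equal(m$flagged, "k")
  expect_true(is.na(m$rho["x", "k"]))
})

test_that("the analysis frame ties E%, g/kg and the cutoff together", {
  co <- shared_cohort()
  filtered <- apply_exclusions(co$participants, co$entries)
  frame <- build_analysis_frame(filtered$participants, filtered$entries)
  expect_equal(frame$protein_e_pct,
               frame$daily_protein_g * 17 / frame$daily_energy_kj * 100)
  expect_equal(frame$meets_cutoff, frame$g_per_kg >= 1.1)
  expect_true(all(c("dp1", "dp2", "dp3") %in% names(frame)))
  expect_equal(frame$breakfast + frame$lunch + frame$dinner + frame$other,
               frame$daily_protein_g)
  .shared$frame <- frame  # reuse in later blocks
})

test_that("the logistic suite reports ORs on the stated units", {
  frame <- .shared$frame
  men <- frame[frame$sex == "male", ]
  res <- fit_logistic_suite(men)
  expect_true(all(c("daily-individual", "daily-mutual", "meal-individual",
                    "meal-mutual", "pattern-individual", "pattern-mutual")
                  %in% res$model))
  ok <- !is.na(res$or)
  expect_true(all(res$ci_lo[ok] <= res$or[ok] & res$or[ok] <= res$ci_hi[ok]))
  expect_true(all(res$or[ok] > 0))
  # adjustment sets follow the reporting design: daily-individual models
  # adjust for age and education only; meal models add energy and EDO
  expect_false(any(grepl("energy_mj",
                         res$adjustment[res$model == "daily-individual"])))
  expect_true(all(grepl("energy_mj",
                        res$adjustment[res$model == "meal-individual"])))
  # per-5g OR equals exp(5 * per-gram log-odds) from a direct refit
  d <- men
  d$education <- factor(d$education)
  fit1 <- glm(meets_cutoff ~ I(daily_protein_g / 5) + age + education,
              family = binomial(), data = d)
  or_direct <- exp(coef(fit1)[2])
  or_suite <- res$or[res$model == "daily-individual" &
                       res$term == "protein_5g"]
  expect_equal(unname(or_suite), unname(or_direct), tolerance = 1e-8)
  fitg <- glm(meets_cutoff ~ daily_protein_g + age + education,
              family = binomial(), data = d)
  expect_equal(unname(or_direct), unname(exp(5 * coef(fitg)[2])),
               tolerance = 1e-8)
})

test_that("planted coefficients are recovered and a constant outcome errors", {
  f <- generate_logistic_fixture(4000, c(-0.2, log(2.0)), seed = 33)
  frame <- tibble::tibble(
    meets_cutoff = f$y,
    daily_protein_g = 5 * f$x[, 2],  # per-5g unit carries the planted OR
    energy_mj = rnorm(4000), total_edo = rnorm(4000),
    breakfast = 0, lunch = 0, dinner = 0, other = 0,
    age = rnorm(4000, 68, 5),
    education = sample(c("primary", "secondary", "university"), 4000, TRUE)
  )
  res <- fit_logistic_suite(frame)
  or <- res$or[res$model == "daily-individual" & res$term == "protein_5g"]
  expect_gt(or, 1.7)
  expect_lt(or, 2.3)
  frame$meets_cutoff <- 1
  expect_error(fit_logistic_suite(frame), "constant")
})

test_that("report tables cover the four shapes and percentages close", {
  frame <- .shared$frame
  tabs <- build_report(frame)
  expect_named(tabs, c("characteristics", "bolus", "spearman", "models"))
  expect_equal(nrow(tabs$bolus), 8)  # 2 sexes x 4 meals
  pct <- tabs$bolus$pct_attain
  expect_true(all(pct >= 0 & pct <= 100))
  expect_setequal(names(tabs$spearman), c("female", "male"))
})
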