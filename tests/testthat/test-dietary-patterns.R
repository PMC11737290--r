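test_that("the food-group matrix averages grams over recorded days", {
  entries <- dplyr::bind_rows(
    lapply(1:4, function(d) dplyr::bind_rows(
      make_entries(day = d, food_group = "bread", weight = 200,
                   meal_label = "breakfast", time = 465L),
      make_entries(day = d, food_group = "fish", weight = c(100, 0, 100, 0)[d],
                   meal_label = "dinner", time = 1095L)
    ))
  )
  participants <- make_participants()
  fgm <- build_foodgroup_matrix(entries, participants)
  expect_equal(unname(fgm$x["P1", "bread"]), 200)
  expect_equal(unname(fgm$x["P1", "fish"]), 50)
  expect_equal(unname(fgm$x["P1", "legume"]), 0)  # unconsumed -> 0, not NA
  expect_equal(ncol(fgm$x), 25)                   # 27 minus other/supplements
  entries$food_group[1] <- "unknown_code"
  expect_error(build_foodgroup_matrix(entries, participants), "unknown")
})

test_that("the log transform is ln(x+1), monotone, and single-shot", {
  fgm <- structure(list(x = matrix(c(0, exp(1) - 1, 10, 100), 2, 2,
                                   dimnames = list(c("a", "b"),
                                                   c("g1", "g2"))),
                        transform = "raw"), class = "foodgroup_matrix")
  lg <- log_transform(fgm)
  expect_equal(lg$x[1, 1], 0)
  expect_equal(lg$x[2, 1], 1)
  expect_true(all(diff(log(sort(c(3, 7, 20)) + 1)) > 0))
  expect_error(log_transform(lg), "already")
})

test_that("correlation PCA satisfies spectral and rotation invariants", {
  co <- shared_cohort()
  filtered <- apply_exclusions(co$participants, co$entries)
  fgm <- log_transform(build_foodgroup_matrix(filtered$entries,
                                              filtered$participants))
  dp <- pca_varimax(fgm)
  p <- ncol(fgm$x)
  expect_equal(sum(dp$eigenvalues), p, tolerance = 1e-6)
  expect_true(all(dp$retained_analysis %in% dp$retained_graphical))
  # orthogonal rotation preserves the variance explained by the block
  unrot <- pca_varimax(fgm, rotate = FALSE)
  expect_equal(sum(dp$loadings^2), sum(unrot$loadings^2), tolerance = 1e-8)
  # deterministic sign convention: dominant loading positive
  for (j in seq_len(ncol(dp$loadings))) {
    expect_gt(dp$loadings[which.max(abs(dp$loadings[, j])), j], 0)
  }
  expect_equal(unname(apply(dp$scores, 2, sd)), rep(1, ncol(dp$scores)))
})

test_that("planted three-factor structure is recovered after rotation", {
  co <- shared_cohort()
  filtered <- apply_exclusions(co$participants, co$entries)
  fgm <- log_transform(build_foodgroup_matrix(filtered$entries,
                                              filtered$participants))
  dp <- pca_varimax(fgm)
  truth <- co$truth$pattern_loadings
  est <- dp$loadings[rownames(truth), seq_len(ncol(truth)), drop = FALSE]
  cong <- factor_congruence(est, truth)
  expect_true(all(cong$congruence > 0.9))
})

test_that("zero-variance columns are dropped with a warning", {
  set.seed(8)
  x <- cbind(matrix(rnorm(200), 50), constant = 1)
  colnames(x) <- c(paste0("g", 1:4), "constant")
  rownames(x) <- paste0("p", 1:50)
  fgm <- structure(list(x = exp(x), transform = "raw"),
                   class = "foodgroup_matrix")
  expect_warning(res <- pca_varimax(log_transform(fgm)), "constant")
  expect_false("constant" %in% rownames(res$loadings))
})

test_that("adherence tertiles follow the documented quantile convention", {
  expect_equal(as.integer(table(adherence_tertiles(1:9))), c(3L, 3L, 3L))
  expect_equal(as.integer(table(adherence_tertiles(rnorm(10)))), c(4L, 3L, 3L))
  expect_warning(t1 <- adherence_tertiles(rep(2, 5)), "equal")
  expect_equal(t1, rep(1L, 5))
  expect_error(adherence_tertiles(c(1, 2)), "at least 3")
  # ranked order respected: lowest scores in tertile 1
  sc <- c(5, 1, 9, 2, 8, 3, 7, 4, 6)
  expect_equal(adherence_tertiles(sc)[sc <= 3], rep(1L, 3))
})
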