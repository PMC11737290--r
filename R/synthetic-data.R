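default_meal_protein <- function() {
  list(
    male = list(breakfast = c(mean = 17.3, sd = 7.5),
                lunch = c(mean = 23.2, sd = 12.4),
                dinner = c(mean = 33.4, sd = 15.0),
                other = c(mean = 10.4, sd = 8.4)),
    female = list(breakfast = c(mean = 14.0, sd = 6.4),
                  lunch = c(mean = 20.0, sd = 11.5),
                  dinner = c(mean = 27.4, sd = 11.3),
                  other = c(mean = 8.9, sd = 7.4))
  )
}

default_anthropometry <- function() {
  list(
    male = list(age = c(mean = 68, sd = 6), height = c(mean = 1.78, sd = 0.07),
                weight = c(mean = 84, sd = 12)),
    female = list(age = c(mean = 68, sd = 5), height = c(mean = 1.65, sd = 0.06),
                  weight = c(mean = 69, sd = 11))
  )
}

default_meal_times <- function() {
  list(breakfast = c(mean = 7.5, sd = 0.75),
       lunch = c(mean = 12.5, sd = 0.75),
       dinner = c(mean = 18.0, sd = 1.0))
}

default_gram_baseline <- function(groups) {
  g <- c(meat = 120, fish = 50, egg = 25, milk_yoghurt = 250, cheese = 30,
         bread = 90, porridge_cereals = 40, pasta_rice = 80, potatoes = 100,
         vegetables = 120, fruit = 130, legume = 10, nuts_seeds = 8,
         cake_dessert = 50, sweets_chocolate = 15, sugar_jam = 20,
         fat_oil = 20, sauce = 40, soup = 60, coffee = 450, tea = 150,
         juice = 80, soft_drink = 100, alcoholic_beverage = 150, snacks = 15)
  out <- g[groups]
  out[is.na(out)] <- 50
  names(out) <- groups
  out
}

#' Default planted dietary-pattern loadings
#'
#' A sparse 25-group x 3-factor loading matrix at the scale of published
#' a-posteriori patterns in older Swedish adults: factor 1 loads bread,
#' potatoes and cheese; factor 2 porridge/cereals, milk/yoghurt and
#' cake/dessert; factor 3 vegetables and fruit.
#'
#' @param groups Character vector of PCA-eligible group codes.
#' @return Numeric matrix, groups x 3.
#' @export
default_pattern_loadings <- function(groups) {
  L <- matrix(0, length(groups), 3, dimnames = list(groups, paste0("F", 1:3)))
  set_l <- function(f, codes, v = 0.8) {
    codes <- intersect(codes, groups)
    L[codes, f] <<- v
  }
  set_l(1, c("bread", "potatoes", "cheese"))
  set_l(1, c("fat_oil", "sauce"), 0.5)
  set_l(2, c("porridge_cereals", "milk_yoghurt", "cake_dessert"))
  set_l(2, c("sugar_jam", "coffee"), 0.5)
  set_l(3, c("vegetables", "fruit"))
  set_l(3, c("legume", "nuts_seeds", "tea"), 0.5)
  L
}

default_meal_affinity <- function(groups) {
  # relative weight of each food group at each main meal / as a snack
  A <- matrix(0.02, length(groups), 4,
              dimnames = list(groups, MEAL_LEVELS))
  put <- function(codes, meal, v) {
    codes <- intersect(codes, groups)
    A[codes, meal] <<- v
  }
  put(c("milk_yoghurt", "porridge_cereals", "bread", "cheese", "egg",
        "sugar_jam", "coffee", "juice", "fruit"), "breakfast", 1)
  put(c("meat", "fish", "potatoes", "pasta_rice", "vegetables", "sauce",
        "soup", "legume", "bread", "fat_oil"), "lunch", 1)
  put(c("meat", "fish", "potatoes", "pasta_rice", "vegetables", "sauce",
        "legume", "fat_oil", "alcoholic_beverage"), "dinner", 1)
  put(c("coffee", "tea", "cake_dessert", "fruit", "sweets_chocolate",
        "snacks", "soft_drink"), "other", 1)
  A
}

check_prob <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("invalid probability vector for %s (must be nonnegative and sum to 1)",
                 what))
  }
}

#' Configuration for the synthetic-cohort generator
#'
#' Defaults are calibrated to the scale of a national 4-day food-record
#' survey of adults aged 60-80: three daily energy peaks, per-meal protein
#' means/SDs by sex, about 4.7 eating occasions per day, food-group
#' mixtures per meal, and a planted low-rank food-group covariance so
#' dietary-pattern recovery can be verified against known truth.  The
#' defaults are a calibration of scale, not ground truth.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed; mandatory, no silent nondeterminism.
#' @param sex_ratio Fraction male, default 0.47.
#' @param n_days Recording days per participant, default 4.
#' @param anthropometry Per-sex mean/SD of age (yr), height (m), weight (kg).
#' @param meal_times Mean clock-hour and SD per main meal.
#' @param meal_protein Per-sex, per-meal mean/SD of daily protein (g).
#' @param snack_rate Expected snacks per day (Poisson), default 1.7.
#' @param meal_e_pct Percent of meal energy from protein, per meal; ties
#'   energy to protein so EDO thresholds are exercised realistically.
#' @param energy_noise_sd SD of multiplicative (log-scale) energy noise.
#' @param pattern_loadings Planted food-group factor matrix (groups x k).
#' @param factor_scale Scale applied to planted loadings on the log-gram
#'   scale, default 0.8.
#' @param gram_noise_sd SD of log-gram idiosyncratic noise, default 0.5.
#' @param missingness_rate Fraction of participants with missing height or
#'   weight, default 0.03.
#' @param day_corr Within-person day-to-day correlation of meal protein on
#'   the log scale, default 0 (no published value; exposed as a parameter).
#' @param education_probs Probabilities of primary/secondary/university.
#' @param codebook Food-group codebook.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants,
                          seed,
                          sex_ratio = 0.47,
                          n_days = 4,
                          anthropometry = default_anthropometry(),
                          meal_times = default_meal_times(),
                          meal_protein = default_meal_protein(),
                          snack_rate = 1.7,
                          meal_e_pct = c(breakfast = 15, lunch = 19,
                                         dinner = 19, other = 13),
                          energy_noise_sd = 0.10,
                          pattern_loadings = NULL,
                          factor_scale = 0.8,
                          gram_noise_sd = 0.5,
                          missingness_rate = 0.03,
                          day_corr = 0,
                          education_probs = c(primary = 0.22,
                                              secondary = 0.45,
                                              university = 0.33),
                          codebook = food_group_codebook()) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("seed is mandatory: pass an integer seed")
  }
  stopifnot(n_participants >= 1, n_days >= 1, snack_rate >= 0,
            sex_ratio >= 0, sex_ratio <= 1,
            missingness_rate >= 0, missingness_rate < 1,
            day_corr >= 0, day_corr < 1,
            energy_noise_sd >= 0, gram_noise_sd >= 0)
  check_prob(education_probs, "education")
  for (sx in c("male", "female")) {
    for (m in MEAL_LEVELS) {
      v <- meal_protein[[sx]][[m]]
      if (v["sd"] < 0 || v["mean"] <= 0) stop("invalid meal_protein for ", m)
    }
  }
  groups <- codebook$code[!codebook$pca_excluded]
  if (is.null(pattern_loadings)) {
    pattern_loadings <- default_pattern_loadings(groups)
  }
  stopifnot(nrow(pattern_loadings) == length(groups))
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    sex_ratio = sex_ratio, n_days = as.integer(n_days),
    anthropometry = anthropometry, meal_times = meal_times,
    meal_protein = meal_protein, snack_rate = snack_rate,
    meal_e_pct = meal_e_pct, energy_noise_sd = energy_noise_sd,
    pattern_loadings = pattern_loadings, factor_scale = factor_scale,
    gram_noise_sd = gram_noise_sd, missingness_rate = missingness_rate,
    day_corr = day_corr, education_probs = education_probs,
    codebook = codebook, groups = groups,
    gram_baseline = default_gram_baseline(groups),
    meal_affinity = default_meal_affinity(groups)
  ), class = "cohort_config")
}

# lognormal parameters matching a target mean and SD
lnorm_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

snap_grid <- function(hours) {
  m <- round(hours * 60 / 15) * 15
  pmin(pmax(m, 0L), 1425L)
}

#' Generate a seeded synthetic cohort of 4-day food diaries
#'
#' Draws participants (anthropometry, education, optional missing
#' height/weight), then for each recorded day: three main meals at grid-
#' snapped clock times with lognormal protein at the configured per-sex
#' means/SDs, Poisson-distributed snacks pooled under the "other" label,
#' meal energy tied to protein through the configured protein-E% targets,
#' and food-group item weights generated from a planted low-rank factor
#' model on the log-gram scale (injected before item assembly).  Meal
#' protein and energy are split across the meal's items proportionally to
#' item weight.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort`: `participants`, `entries`
#'   (diary tibble), and `truth` (planted per-meal protein parameters,
#'   factor loadings and per-participant factor scores).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 20, seed = 42))
#' nrow(cohort$participants)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("P%05d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
  draw <- function(sx, field) {
    p <- config$anthropometry[[sx]][[field]]
    stats::rnorm(1, p["mean"], p["sd"])
  }
  age <- numeric(n); height <- numeric(n); weight <- numeric(n)
  for (i in seq_len(n)) {
    age[i] <- min(max(draw(sex[i], "age"), 60), 80)
    height[i] <- min(max(draw(sex[i], "height"), 1.45), 2.05)
    weight[i] <- max(draw(sex[i], "weight"), 40)
  }
  education <- sample(names(config$education_probs), n, replace = TRUE,
                      prob = config$education_probs)
  # injected missingness exercises the exclusion filters downstream
  miss <- stats::runif(n) < config$missingness_rate
  which_field <- stats::runif(n) < 0.5
  height[miss & which_field] <- NA
  weight[miss & !which_field] <- NA

  participants <- tibble::tibble(
    id = ids, sex = sex, age = round(age, 1),
    height = round(height, 2), weight = round(weight, 1),
    education = education
  )

  k <- ncol(config$pattern_loadings)
  fscores <- matrix(stats::rnorm(n * k), n, k,
                    dimnames = list(ids, colnames(config$pattern_loadings)))
  groups <- config$groups
  log_base <- log(config$gram_baseline)
  affinity <- config$meal_affinity
  if (config$snack_rate == 0) affinity[, "other"] <- 0
  main_aff <- affinity[, MAIN_MEALS, drop = FALSE]
  main_aff <- main_aff / rowSums(main_aff)
  snack_mix <- affinity[, "other"]
  if (sum(snack_mix) > 0) snack_mix <- snack_mix / sum(snack_mix)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sx <- sex[i]
    mp <- config$meal_protein[[sx]]
    # participant-level random effect implements day-to-day correlation
    re <- stats::rnorm(length(MEAL_LEVELS))
    names(re) <- MEAL_LEVELS
    day_rows <- vector("list", config$n_days)
    for (d in seq_len(config$n_days)) {
      # planted factor structure on the log-gram scale, before item assembly
      lg <- log_base + config$factor_scale *
        as.numeric(config$pattern_loadings %*% fscores[i, ]) +
        stats::rnorm(length(groups), 0, config$gram_noise_sd)
      grams <- exp(lg)
      names(grams) <- groups
      meal_of_group <- vapply(groups, function(g) {
        sample(MAIN_MEALS, 1, prob = main_aff[g, ])
      }, character(1))

      meal_list <- list()
      for (m in MAIN_MEALS) {
        pars <- lnorm_params(mp[[m]]["mean"], mp[[m]]["sd"])
        zlog <- sqrt(config$day_corr) * re[m] +
          sqrt(1 - config$day_corr) * stats::rnorm(1)
        protein <- exp(pars$mu + pars$sigma * zlog)
        tm <- config$meal_times[[m]]
        time <- snap_grid(stats::rnorm(1, tm["mean"], tm["sd"]))
        gset <- groups[meal_of_group == m]
        if (!length(gset)) gset <- sample(groups, 1)
        w <- grams[gset]
        energy <- protein * 17 / (config$meal_e_pct[m] / 100) *
          exp(stats::rnorm(1, 0, config$energy_noise_sd))
        meal_list[[m]] <- tibble::tibble(
          participant_id = ids[i], day = d, time = as.integer(time),
          meal_label = m, food_group = gset,
          weight = as.numeric(w),
          energy = as.numeric(energy * w / sum(w)),
          protein = as.numeric(protein * w / sum(w))
        )
      }
      n_snacks <- stats::rpois(1, config$snack_rate)
      if (n_snacks > 0 && sum(snack_mix) > 0) {
        # each snack is an independent intake at its own clock hour, so the
        # expected daily "other" total is snack_rate * per-snack mean
        pars <- lnorm_params(mp[["other"]]["mean"] / max(config$snack_rate, 1),
                             mp[["other"]]["sd"] / max(config$snack_rate, 1))
        zlog <- sqrt(config$day_corr) * re["other"] +
          sqrt(1 - config$day_corr) * stats::rnorm(n_snacks)
        sprotein <- exp(pars$mu + pars$sigma * zlog)
        sg <- sample(groups, n_snacks, replace = TRUE, prob = snack_mix)
        shours <- sample(c(9:11, 14:16, 20:22), min(n_snacks, 9))
        shours <- rep_len(shours, n_snacks)
        stimes <- snap_grid(shours + sample(0:3, n_snacks, TRUE) / 4)
        senergy <- sprotein * 17 / (config$meal_e_pct["other"] / 100) *
          exp(stats::rnorm(n_snacks, 0, config$energy_noise_sd))
        meal_list[["other"]] <- tibble::tibble(
          participant_id = ids[i], day = d, time = as.integer(stimes),
          meal_label = "other", food_group = sg,
          weight = as.numeric(config$gram_baseline[sg] *
                                exp(stats::rnorm(n_snacks, -0.5, 0.5))),
          energy = as.numeric(senergy),
          protein = as.numeric(sprotein)
        )
      }
      day_rows[[d]] <- dplyr::bind_rows(meal_list)
    }
    rows[[i]] <- dplyr::bind_rows(day_rows)
  }
  entries <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$participant_id, .data$day, .data$time)

  structure(list(
    participants = participants,
    entries = entries,
    truth = list(
      meal_protein = config$meal_protein,
      pattern_loadings = config$pattern_loadings,
      factor_scores = fscores,
      seed = config$seed
    )
  ), class = "synthetic_cohort")
}

#' Generate a logistic-regression test fixture with known coefficients
#'
#' Covariates are standard normal; outcomes are Bernoulli with
#' P(y = 1) = logit^-1(X beta), where X carries an intercept column.  Used
#' to verify estimator recovery and confidence-interval coverage.
#'
#' @param n Number of observations (>= 1).
#' @param coefficients Numeric vector: intercept followed by covariate
#'   coefficients (log-odds scale).
#' @param seed Integer seed (mandatory).
#' @return A list: `x` (n x p design matrix incl. intercept), `y` (0/1
#'   outcomes), `coefficients` (the planted truth).
#' @export
generate_logistic_fixture <- function(n, coefficients, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) stop("seed is mandatory")
  stopifnot(n >= 1, length(coefficients) >= 1)
  set.seed(seed)
  p <- length(coefficients)
  x <- cbind(intercept = 1,
             matrix(stats::rnorm(n * (p - 1)), n, p - 1,
                    dimnames = list(NULL, paste0("x", seq_len(p - 1)))))
  eta <- drop(x %*% coefficients)
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  list(x = x, y = y, coefficients = coefficients)
}
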