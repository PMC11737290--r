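# Independent oracles and fixture builders.  These deliberately avoid the
# package's own aggregation code paths.

# literal re-implementation of the hourly/EDO rules: clock hour h collects
# items at (h-1):30, (h-1):45, h:00 and h:15; an hour is an EDO when its
# energy strictly exceeds 210 kJ, large when it holds >= 15% of daily energy
brute_edo_day <- function(times, energies) {
  hourly <- numeric(24)
  for (h in 0:23) {
    slots <- c(((h - 1) * 60 + 30) %% 1440, ((h - 1) * 60 + 45) %% 1440,
               h * 60, h * 60 + 15)
    hourly[h + 1] <- sum(energies[times %in% slots])
  }
  daily <- sum(hourly)
  flags <- character(24)
  for (h in 1:24) {
    if (daily > 0 && hourly[h] > 210) {
      flags[h] <- if (hourly[h] >= 0.15 * daily) "large" else "small"
    } else {
      flags[h] <- "none"
    }
  }
  list(hourly = hourly, flags = flags)
}

# Spearman via explicit average ranks then the Pearson product-moment formula
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Pearson chi-square by the definitional formula sum (O - E)^2 / E
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

make_entries <- function(participant_id = "P1", day = 1L, time = 720L,
                         meal_label = "lunch", food_group = "meat",
                         weight = 100, energy = 1000, protein = 20) {
  tibble::tibble(participant_id = participant_id, day = as.integer(day),
                 time = as.integer(time), meal_label = meal_label,
                 food_group = food_group, weight = weight, energy = energy,
                 protein = protein)
}

make_participants <- function(id = "P1", sex = "male", age = 68,
                              height = 1.75, weight = 80,
                              education = "secondary") {
  tibble::tibble(id = id, sex = sex, age = age, height = height,
                 weight = weight, education = education)
}

# one mid-size cohort shared across test files, generated once per run
.shared <- new.env(parent = emptyenv())
shared_cohort <- function() {
  if (is.null(.shared$cohort)) {
    .shared$cohort <- generate_cohort(cohort_config(n_participants = 500,
                                                    seed = 101))
  }
  .shared$cohort
}
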