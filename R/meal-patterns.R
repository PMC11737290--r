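EDO_KJ <- 210
LARGE_EDO_FRACTION <- 0.15
BOLUS_G <- 30

hour_slot <- function(time) {
  ((time + 30) %/% 60) %% 24
}

#' Aggregate diary entries to hourly energy/protein profiles
#'
#' Clock hour h collects the items recorded at (h-1):30, (h-1):45, h:00 and
#' h:15 — e.g. foods at 6:30, 6:45, 7:00 and 7:15 count as intake at 7
#' o'clock.  Items at 23:30/23:45 wrap to hour 0 of the same recorded day,
#' keeping each day self-contained.
#'
#' @param entries Diary entry tibble (possibly several participants/days);
#'   times in minutes from midnight on the 15-minute grid.
#' @return A long tibble with all 24 hours for every participant-day (zero
#'   rows included): `participant_id`, `day`, `hour` (0-23), `energy` (kJ),
#'   `protein` (g), plus per-day totals `daily_energy`, `daily_protein`.
#' @export
hourly_aggregate <- function(entries) {
  if (any(entries$time %% 15 != 0)) stop("entry time off the 15-min grid")
  days <- dplyr::distinct(entries, .data$participant_id, .data$day)
  grid <- tidyr::crossing(days, hour = 0:23)
  hourly <- entries |>
    dplyr::mutate(hour = hour_slot(.data$time)) |>
    dplyr::group_by(.data$participant_id, .data$day, .data$hour) |>
    dplyr::summarise(energy = sum(.data$energy),
                     protein = sum(.data$protein), .groups = "drop")
  grid |>
    dplyr::left_join(hourly, by = c("participant_id", "day", "hour")) |>
    dplyr::mutate(energy = dplyr::coalesce(.data$energy, 0),
                  protein = dplyr::coalesce(.data$protein, 0)) |>
    dplyr::group_by(.data$participant_id, .data$day) |>
    dplyr::mutate(daily_energy = sum(.data$energy),
                  daily_protein = sum(.data$protein)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$participant_id, .data$day, .data$hour)
}

#' Classify hours into eating and drinking occasions (EDOs)
#'
#' An hour is an EDO when its energy exceeds 210 kJ (strict; 210 kJ exactly
#' is not an EDO).  An EDO holding at least 15% of that day's energy intake
#' is a large EDO (inclusive); below 15% it is small.  A day with zero total
#' energy has no EDOs.
#'
#' @param profile Output of [hourly_aggregate()].
#' @param edo_kj EDO energy threshold in kJ, default 210.
#' @param large_fraction Large-EDO share of daily energy, default 0.15.
#' @return `profile` with an added `edo` factor column
#'   (`none`/`small`/`large`).
#' @export
classify_edos <- function(profile, edo_kj = EDO_KJ,
                          large_fraction = LARGE_EDO_FRACTION) {
  is_edo <- profile$energy > edo_kj & profile$daily_energy > 0
  is_large <- is_edo & profile$energy >= large_fraction * profile$daily_energy
  profile$edo <- factor(
    ifelse(is_large, "large", ifelse(is_edo, "small", "none")),
    levels = c("none", "small", "large")
  )
  profile
}

#' Mean EDO counts per day, per participant
#'
#' Counts total/large/small EDOs for each recorded day and averages over the
#' participant's recorded days.
#'
#' @param profile Output of [classify_edos()].
#' @return Tibble: `participant_id`, `total_edo`, `large_edo`, `small_edo`
#'   (mean counts/day).
#' @export
edo_summary <- function(profile) {
  stopifnot("edo" %in% names(profile))
  profile |>
    dplyr::group_by(.data$participant_id, .data$day) |>
    dplyr::summarise(large = sum(.data$edo == "large"),
                     small = sum(.data$edo == "small"), .groups = "drop") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(total_edo = mean(.data$large + .data$small),
                     large_edo = mean(.data$large),
                     small_edo = mean(.data$small), .groups = "drop")
}

#' Per-participant protein by self-indicated meal
#'
#' Protein is summed within each recorded day by meal label (breakfast,
#' lunch, dinner, other) and averaged over the participant's recorded days;
#' a meal never reported contributes 0 to its mean.  Bolus flags mark meals
#' whose across-day mean reaches 30 g.  The coefficient of variation is the
#' sample standard deviation divided by the mean of the three main-meal
#' means, a measure of how skewed protein is across breakfast, lunch and
#' dinner.
#'
#' @param entries Diary entries with normalised meal labels.
#' @param profile Optional pre-computed output of [classify_edos()]; if
#'   supplied, EDO means are merged into the summary.
#' @param bolus_g Bolus threshold in g, default 30.
#' @return Tibble, one row per participant: meal means `breakfast`, `lunch`,
#'   `dinner`, `other` (g), `daily_protein_g`, bolus flags
#'   `bolus_breakfast` ... `bolus_other`, `cv`, and EDO means when `profile`
#'   is given.
#' @export
meal_protein_summary <- function(entries, profile = NULL, bolus_g = BOLUS_G) {
  entries$meal_label <- normalise_meal_label(entries$meal_label)
  per_day <- entries |>
    dplyr::group_by(.data$participant_id, .data$day, .data$meal_label) |>
    dplyr::summarise(protein = sum(.data$protein), .groups = "drop") |>
    tidyr::complete(
      tidyr::nesting(participant_id, day),
      meal_label = MEAL_LEVELS, fill = list(protein = 0)
    )
  means <- per_day |>
    dplyr::group_by(.data$participant_id, .data$meal_label) |>
    dplyr::summarise(protein = mean(.data$protein), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "meal_label", values_from = "protein",
                       values_fill = 0)
  for (m in MEAL_LEVELS) {
    if (!m %in% names(means)) means[[m]] <- 0
  }
  main <- as.matrix(means[, MAIN_MEALS])
  mu <- rowMeans(main)
  sdv <- apply(main, 1, stats::sd)
  out <- means |>
    dplyr::mutate(
      daily_protein_g = .data$breakfast + .data$lunch + .data$dinner +
        .data$other,
      bolus_breakfast = .data$breakfast >= bolus_g,
      bolus_lunch = .data$lunch >= bolus_g,
      bolus_dinner = .data$dinner >= bolus_g,
      bolus_other = .data$other >= bolus_g,
      cv = ifelse(mu > 0, sdv / mu, NA_real_)
    )
  if (!is.null(profile)) {
    out <- dplyr::left_join(out, edo_summary(profile), by = "participant_id")
  }
  out
}

#' Bolus-attainment table by sex and meal
#'
#' For each meal, the share and count of participants whose across-day mean
#' protein reaches the bolus threshold, subgroup means/SDs below and at or
#' above it, and the mean surplus (subgroup mean minus the threshold) among
#' attainers.  Empty strata are reported as `NA`, not zero.
#'
#' @param summaries Output of [meal_protein_summary()] joined with a `sex`
#'   column (see [build_analysis_frame()]), or any tibble with `sex` and the
#'   four meal-mean columns.
#' @param bolus_g Bolus threshold in g.
#' @return Tibble: `sex`, `meal`, `mean`, `sd`, `n`, `pct_attain`,
#'   `n_attain`, `mean_below`, `sd_below`, `mean_attain`, `sd_attain`,
#'   `surplus_g`, `surplus_g_rounded`.
#' @export
bolus_table <- function(summaries, bolus_g = BOLUS_G) {
  long <- summaries |>
    dplyr::select(dplyr::all_of(c("participant_id", "sex", MEAL_LEVELS))) |>
    tidyr::pivot_longer(dplyr::all_of(MEAL_LEVELS), names_to = "meal",
                        values_to = "protein")
  mstat <- function(x) if (length(x)) mean(x) else NA_real_
  sstat <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  long |>
    dplyr::group_by(.data$sex, .data$meal) |>
    dplyr::summarise(
      mean = mean(.data$protein),
      sd = stats::sd(.data$protein),
      n = dplyr::n(),
      n_attain = sum(.data$protein >= bolus_g),
      pct_attain = 100 * .data$n_attain / .data$n,
      mean_below = mstat(.data$protein[.data$protein < bolus_g]),
      sd_below = sstat(.data$protein[.data$protein < bolus_g]),
      mean_attain = mstat(.data$protein[.data$protein >= bolus_g]),
      sd_attain = sstat(.data$protein[.data$protein >= bolus_g]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      surplus_g = .data$mean_attain - bolus_g,
      surplus_g_rounded = round(.data$surplus_g),
      meal = factor(.data$meal, levels = MEAL_LEVELS)
    ) |>
    dplyr::arrange(.data$sex, .data$meal)
}

#' Redistribute surplus dinner protein to lunch
#'
#' A counterfactual: each participant's dinner protein above the bolus
#' threshold is moved onto lunch (dinner is capped at the threshold, lunch
#' gains the surplus), and lunch bolus attainment is re-evaluated.  Total
#' protein is conserved per participant.
#'
#' @param summaries Output of [meal_protein_summary()], optionally with a
#'   `sex` column for stratified proportions.
#' @param bolus_g Bolus threshold in g.
#' @return A list: `participants`, a tibble with `lunch`, `dinner`,
#'   `lunch_after`, `dinner_after`, `transfer`; `attainment`, lunch
#'   attainment proportions before/after (by sex when available);
#'   `total_protein_delta`, the cohort-level conservation check.
#' @export
redistribute_surplus <- function(summaries, bolus_g = BOLUS_G) {
  transfer <- pmax(0, summaries$dinner - bolus_g)
  res <- tibble::tibble(
    participant_id = summaries$participant_id,
    lunch = summaries$lunch, dinner = summaries$dinner,
    transfer = transfer,
    lunch_after = summaries$lunch + transfer,
    dinner_after = summaries$dinner - transfer
  )
  if ("sex" %in% names(summaries)) res$sex <- summaries$sex
  grp <- if ("sex" %in% names(res)) "sex" else character()
  attainment <- res |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      pct_before = 100 * mean(.data$lunch >= bolus_g),
      pct_after = 100 * mean(.data$lunch_after >= bolus_g),
      .groups = "drop"
    )
  list(
    participants = res,
    attainment = attainment,
    total_protein_delta = sum(res$lunch_after + res$dinner_after) -
      sum(res$lunch + res$dinner)
  )
}

#' Association between lunch and dinner bolus attainment
#'
#' Pearson chi-square test (no continuity correction by default) on the 2x2
#' table of lunch-bolus by dinner-bolus flags.  With a zero margin the test
#' is not computed and the result is flagged.
#'
#' @param summaries Output of [meal_protein_summary()].
#' @param correct Apply Yates continuity correction, default `FALSE`.
#' @return A list: `table` (2x2 counts), `statistic`, `p_value`, `computed`.
#' @export
bolus_cross_association <- function(summaries, correct = FALSE) {
  tab <- table(lunch = factor(summaries$bolus_lunch, levels = c(FALSE, TRUE)),
               dinner = factor(summaries$bolus_dinner, levels = c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(table = tab, statistic = NA_real_, p_value = NA_real_,
                computed = FALSE))
  }
  ct <- stats::chisq.test(tab, correct = correct)
  list(table = tab, statistic = unname(ct$statistic),
       p_value = ct$p.value, computed = TRUE)
}
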