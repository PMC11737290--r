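#' Adjusted body weight for overweight participants
#'
#' For BMI above 25 kg/m2 the denominator of protein-per-kg uses an adjusted
#' weight: the weight at BMI 25 plus one quarter of the excess over it,
#'
#'   adjusted = weight_at_BMI25 + 0.25 * (weight - weight_at_BMI25),
#'
#' with weight_at_BMI25 = 25 * height^2.  At or below BMI 25 the observed
#' weight is used unchanged, and the formula is continuous at the threshold.
#'
#' @param weight Body weight in kg (> 0), vectorised.
#' @param height Height in m (> 0), vectorised.
#' @return Adjusted body weight in kg.
#' @export
#' @examples
#' adjusted_body_weight(100, 1.70)  # 79.1875
#' adjusted_body_weight(60, 1.60)   # 60, BMI below 25
adjusted_body_weight <- function(weight, height) {
  if (any(is.na(weight) | is.na(height)) ||
      any(weight <= 0) || any(height <= 0)) {
    stop("weight and height must be positive")
  }
  w25 <- 25 * height^2
  ifelse(weight / height^2 > 25, w25 + 0.25 * (weight - w25), weight)
}

henry_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "henry_bmr_coefficients.csv",
                        package = "mealtrace")
  }
  readr::read_csv(path, col_types = readr::cols(
    sex = readr::col_character(),
    age_min = readr::col_double(),
    age_max = readr::col_double(),
    weight_coef = readr::col_double(),
    height_coef = readr::col_double(),
    intercept = readr::col_double()
  ))
}

#' Basal metabolic rate by the Henry weight-and-height equations
#'
#' BMR (MJ/day) = a * weight + b * height + c, with sex- and age-band
#' specific coefficients read from an editable CSV.  The shipped table
#' carries the published Henry coefficients for ages 60 and over (the
#' population this package targets); ages outside the shipped bands raise
#' an error naming the supported bands.  For overweight participants the
#' adjusted body weight should be supplied.
#'
#' @param sex "male" or "female", vectorised.
#' @param age Age in years.
#' @param weight (Adjusted) body weight in kg.
#' @param height Height in m.
#' @param coefficients Coefficient table; defaults to the shipped CSV.
#' @return BMR in MJ/day.
#' @export
#' @examples
#' bmr_henry("female", 68, 65, 1.63)
bmr_henry <- function(sex, age, weight, height,
                      coefficients = henry_coefficients()) {
  n <- max(length(sex), length(age), length(weight), length(height))
  sex <- rep_len(sex, n); age <- rep_len(age, n)
  weight <- rep_len(weight, n); height <- rep_len(height, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    row <- coefficients[coefficients$sex == sex[i] &
                          age[i] >= coefficients$age_min &
                          age[i] <= coefficients$age_max, ]
    if (nrow(row) == 0) {
      bands <- paste(sprintf("%s %g-%g yr", coefficients$sex,
                             coefficients$age_min, coefficients$age_max),
                     collapse = "; ")
      stop(sprintf("no Henry coefficients for %s aged %g; supported bands: %s",
                   sex[i], age[i], bands))
    }
    row <- row[1, ]
    out[i] <- row$weight_coef * weight[i] + row$height_coef * height[i] +
      row$intercept
  }
  out
}

#' Protein adequacy relative to (adjusted) body weight
#'
#' Divides daily protein intake by the (adjusted) body weight and flags
#' whether the ratio reaches the 1.1 g/kg/day cutoff (inclusive).
#'
#' @param daily_protein Protein intake in g/day.
#' @param adjusted_weight Denominator weight in kg (> 0).
#' @param cutoff Adequacy threshold in g/kg/day, default 1.1.
#' @return Tibble with `g_per_kg` and logical `meets_cutoff`.
#' @export
protein_adequacy <- function(daily_protein, adjusted_weight, cutoff = 1.1) {
  if (any(adjusted_weight <= 0)) stop("adjusted_weight must be positive")
  g_per_kg <- daily_protein / adjusted_weight
  tibble::tibble(g_per_kg = g_per_kg, meets_cutoff = g_per_kg >= cutoff)
}

#' Per-participant anthropometry-derived quantities
#'
#' Combines BMI, adjusted body weight, Henry BMR, physical-activity-level
#' proxy (reported energy intake / BMR, descriptive only), daily protein per
#' kg adjusted weight and the adequacy flag.  Daily protein and energy are
#' means over the participant's recorded days.
#'
#' @param participants Participant tibble (post-exclusion: height and weight
#'   present).
#' @param entries Diary entries of those participants.
#' @param cutoff Adequacy cutoff in g/kg/day.
#' @param coefficients Henry coefficient table.
#' @return Tibble, one row per participant: `id`, `sex`, `bmi`,
#'   `weight_at_bmi25`, `adjusted_weight`, `bmr_mj`, `pal`,
#'   `daily_energy_kj`, `daily_protein_g`, `protein_e_pct`, `g_per_kg`,
#'   `meets_cutoff`.
#' @export
anthropometry_table <- function(participants, entries, cutoff = 1.1,
                                coefficients = henry_coefficients()) {
  daily <- entries |>
    dplyr::group_by(.data$participant_id, .data$day) |>
    dplyr::summarise(energy = sum(.data$energy),
                     protein = sum(.data$protein), .groups = "drop") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(daily_energy_kj = mean(.data$energy),
                     daily_protein_g = mean(.data$protein),
                     .groups = "drop")
  p <- dplyr::inner_join(participants, daily,
                         by = c(id = "participant_id"))
  if (any(is.na(p$height) | is.na(p$weight))) {
    stop("anthropometry requires height and weight; run apply_exclusions() first")
  }
  adj <- adjusted_body_weight(p$weight, p$height)
  bmr <- bmr_henry(p$sex, p$age, adj, p$height, coefficients)
  adequacy <- protein_adequacy(p$daily_protein_g, adj, cutoff)
  tibble::tibble(
    id = p$id, sex = p$sex,
    bmi = p$weight / p$height^2,
    weight_at_bmi25 = 25 * p$height^2,
    adjusted_weight = adj,
    bmr_mj = bmr,
    pal = (p$daily_energy_kj / 1000) / bmr,
    daily_energy_kj = p$daily_energy_kj,
    daily_protein_g = p$daily_protein_g,
    protein_e_pct = protein_energy_pct(p$daily_protein_g, p$daily_energy_kj),
    g_per_kg = adequacy$g_per_kg,
    meets_cutoff = adequacy$meets_cutoff
  )
}

#' Percent of energy from protein
#'
#' Uses 17 kJ per gram of protein (the standard metabolisable-energy factor
#' in kJ); the factor is configurable since nutrient databases differ.
#'
#' @param protein_g Protein in g/day.
#' @param energy_kj Energy in kJ/day.
#' @param kj_per_g Energy-conversion factor, default 17 kJ/g.
#' @return E% on the 0-100 scale.
#' @export
protein_energy_pct <- function(protein_g, energy_kj, kj_per_g = 17) {
  ifelse(energy_kj > 0, protein_g * kj_per_g / energy_kj * 100, NA_real_)
}
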