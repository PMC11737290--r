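#' Food-group codebook
#'
#' Returns the 27-group codebook used to classify diary items.  Two groups
#' ("other" and "supplements") are flagged `pca_excluded`: "other" pools a
#' very mixed range of culinary ingredients and "supplements" has few
#' consumers, so both are left out of the dietary-pattern analysis, leaving
#' 25 groups.
#'
#' @param path Optional path to an alternative codebook CSV with columns
#'   `code`, `name`, `pca_excluded`.  Defaults to the codebook shipped with
#'   the package.
#' @return A tibble with columns `code`, `name`, `pca_excluded`.
#' @export
#' @examples
#' cb <- food_group_codebook()
#' nrow(cb)          # 27
#' sum(!cb$pca_excluded)  # 25 enter the PCA
food_group_codebook <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "food_groups.csv", package = "mealtrace")
  }
  cb <- readr::read_csv(path, col_types = readr::cols(
    code = readr::col_character(),
    name = readr::col_character(),
    pca_excluded = readr::col_logical()
  ))
  if (anyDuplicated(cb$code)) stop("duplicate food-group codes in codebook")
  cb
}

MAIN_MEALS <- c("breakfast", "lunch", "dinner")
MEAL_LEVELS <- c(MAIN_MEALS, "other")

KJ_PER_KCAL <- 4.184

#' Normalise self-indicated meal labels
#'
#' Labels other than breakfast/lunch/dinner (case-insensitive) are pooled
#' into `"other"`, the catch-all for foods consumed outside the three main
#' meals.
#'
#' @param x Character vector of meal labels.
#' @return Character vector over `breakfast`, `lunch`, `dinner`, `other`.
#' @export
normalise_meal_label <- function(x) {
  if (any(is.na(x) | !nzchar(trimws(x)))) {
    stop("missing or empty meal label")
  }
  x <- tolower(trimws(x))
  ifelse(x %in% MAIN_MEALS, x, "other")
}

#' Validate a diary entry table
#'
#' Checks the invariants of the entry schema: times on the 15-minute grid in
#' [0, 1440), nonnegative weight/energy/protein, known food-group codes,
#' days >= 1.  Offending rows are reported by row number.
#'
#' @param entries Tibble of diary entries.
#' @param codebook Codebook tibble, see [food_group_codebook()].
#' @return `entries`, invisibly, with meal labels normalised.
#' @export
validate_entries <- function(entries, codebook = food_group_codebook()) {
  required <- c("participant_id", "day", "time", "meal_label", "food_group",
                "weight", "energy", "protein")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols)) {
    stop("diary is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      stop(sprintf("%s in rows: %s", what,
                   paste(utils::head(idx, 10), collapse = ", ")))
    }
  }
  bad(is.na(entries$time) | entries$time %% 15 != 0 |
        entries$time < 0 | entries$time >= 1440,
      "time off the 15-min grid or outside [0, 1440)")
  bad(is.na(entries$day) | entries$day < 1, "invalid day index")
  bad(entries$weight < 0 | entries$energy < 0 | entries$protein < 0,
      "negative weight/energy/protein")
  bad(!(entries$food_group %in% codebook$code), "unknown food-group code")
  entries$meal_label <- normalise_meal_label(entries$meal_label)
  invisible(entries)
}

entry_cols <- function() {
  readr::cols(
    participant_id = readr::col_character(),
    day = readr::col_integer(),
    time = readr::col_integer(),
    meal_label = readr::col_character(),
    food_group = readr::col_character(),
    weight = readr::col_double(),
    energy = readr::col_double(),
    protein = readr::col_double()
  )
}

participant_cols <- function() {
  readr::cols(
    id = readr::col_character(),
    sex = readr::col_character(),
    age = readr::col_double(),
    height = readr::col_double(),
    weight = readr::col_double(),
    education = readr::col_character()
  )
}

#' Read a diary and participant table from CSV
#'
#' The diary has one row per consumed item (participant id, recording day,
#' clock time as minutes from midnight on a 15-minute grid, self-indicated
#' meal label, food-group code, weight in g, energy in kJ, protein in g).
#' The participant table carries id, sex, age (years), height (m), weight
#' (kg; may be missing) and education (primary/secondary/university).
#'
#' @param diary_path Path to the entries CSV.
#' @param participants_path Path to the participants CSV.
#' @param codebook Codebook used to validate food-group codes.
#' @return A list with elements `participants` and `entries` (tibbles).
#' @export
read_diary <- function(diary_path, participants_path,
                       codebook = food_group_codebook()) {
  entries <- readr::read_csv(diary_path, col_types = entry_cols())
  participants <- readr::read_csv(participants_path,
                                  col_types = participant_cols())
  entries <- validate_entries(entries, codebook)
  validate_participants(participants)
  list(participants = participants, entries = entries)
}

validate_participants <- function(participants) {
  stopifnot(all(c("id", "sex", "age", "height", "weight", "education") %in%
                  names(participants)))
  if (anyDuplicated(participants$id)) stop("duplicate participant ids")
  if (!all(participants$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  with_h <- !is.na(participants$height)
  if (any(participants$height[with_h] <= 0.5 | participants$height[with_h] >= 2.5)) {
    stop("height outside plausible range (0.5, 2.5) m")
  }
  if (any(participants$weight[!is.na(participants$weight)] <= 0)) {
    stop("nonpositive weight")
  }
  invisible(participants)
}

#' Write a diary and participant table to CSV
#'
#' @param participants,entries Tibbles as returned by [read_diary()] or
#'   [generate_cohort()].
#' @param diary_path,participants_path Output paths.
#' @export
write_diary <- function(participants, entries, diary_path, participants_path) {
  readr::write_csv(entries, diary_path)
  readr::write_csv(participants, participants_path)
  invisible(list(diary = diary_path, participants = participants_path))
}

#' Apply the study's participant exclusion filters
#'
#' A participant is excluded when (in order of precedence) they recorded no
#' intake at all, self-reported height or weight is missing, or mean daily
#' energy intake over the recorded days is extreme: below 800 or above
#' 4000 kcal/day in men, below 500 or above 3500 kcal/day in women
#' (strict inequalities; boundary values are retained).  Energy is stored in
#' kJ and converted at 4.184 kJ/kcal.
#'
#' @param participants Participant tibble.
#' @param entries Diary entry tibble (energy in kJ).
#' @param bands Named list of sex-specific kcal bands,
#'   `list(male = c(lo, hi), female = c(lo, hi))`.
#' @return A list: `participants` (retained rows), `entries` (their rows),
#'   and `log`, a tibble of excluded ids with one primary `reason` each.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 30, seed = 1))
#' filtered <- apply_exclusions(cohort$participants, cohort$entries)
#' nrow(filtered$log)  # excluded participants with reasons
apply_exclusions <- function(participants, entries,
                             bands = list(male = c(800, 4000),
                                          female = c(500, 3500))) {
  daily <- entries |>
    dplyr::group_by(.data$participant_id, .data$day) |>
    dplyr::summarise(energy = sum(.data$energy), .groups = "drop") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(mean_kcal = mean(.data$energy) / KJ_PER_KCAL,
                     .groups = "drop")

  p <- dplyr::left_join(participants, daily,
                        by = c(id = "participant_id"))
  lo <- vapply(p$sex, function(s) bands[[s]][1], numeric(1))
  hi <- vapply(p$sex, function(s) bands[[s]][2], numeric(1))

  reason <- rep(NA_character_, nrow(p))
  reason[is.na(p$mean_kcal)] <- "no intake data"
  need <- is.na(reason) & (is.na(p$height) | is.na(p$weight))
  reason[need] <- "missing height or weight"
  need <- is.na(reason) & (p$mean_kcal < lo | p$mean_kcal > hi)
  reason[need] <- "extreme energy intake"

  keep <- is.na(reason)
  log <- tibble::tibble(id = p$id[!keep], sex = p$sex[!keep],
                        mean_kcal = p$mean_kcal[!keep],
                        reason = reason[!keep])
  list(
    participants = participants[keep, , drop = FALSE],
    entries = entries[entries$participant_id %in% participants$id[keep], ,
                      drop = FALSE],
    log = log
  )
}
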