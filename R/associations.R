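#' Assemble the per-participant analysis frame
#'
#' Joins, for every retained participant: daily energy (MJ) and protein (g),
#' protein E%, protein per kg adjusted body weight and the 1.1 g/kg
#' adequacy flag, meal-specific protein means, meal-protein CV, mean
#' total/large/small EDO counts, dietary-pattern scores (sex-stratified
#' PCA, analysis-retained components, at most `max_patterns`), age, sex and
#' education.
#'
#' @param participants Post-exclusion participant tibble.
#' @param entries Their diary entries.
#' @param cutoff Protein-adequacy cutoff, g/kg/day.
#' @param max_patterns Number of pattern scores to carry, default 3.
#' @param codebook Food-group codebook.
#' @return A tibble, one row per participant.
#' @export
build_analysis_frame <- function(participants, entries, cutoff = 1.1,
                                 max_patterns = 3,
                                 codebook = food_group_codebook()) {
  anthro <- anthropometry_table(participants, entries, cutoff = cutoff)
  profile <- classify_edos(hourly_aggregate(entries))
  meals <- meal_protein_summary(entries, profile)

  frame <- participants |>
    dplyr::select(dplyr::all_of(c("id", "sex", "age", "education"))) |>
    dplyr::inner_join(
      dplyr::select(anthro, dplyr::all_of(c(
        "id", "bmi", "adjusted_weight", "bmr_mj", "pal", "daily_energy_kj",
        "daily_protein_g", "protein_e_pct", "g_per_kg", "meets_cutoff"
      ))), by = "id") |>
    dplyr::inner_join(dplyr::select(meals, -dplyr::any_of("daily_protein_g")),
                      by = c(id = "participant_id")) |>
    dplyr::mutate(energy_mj = .data$daily_energy_kj / 1000)

  # sex-stratified dietary patterns; strata never share scaling parameters
  for (sx in unique(frame$sex)) {
    sub <- participants[participants$sex == sx, , drop = FALSE]
    fgm <- build_foodgroup_matrix(
      entries[entries$participant_id %in% sub$id, , drop = FALSE],
      sub, codebook)
    dp <- pca_varimax(log_transform(fgm))
    use <- seq_len(min(length(dp$retained_analysis), ncol(dp$scores),
                       max_patterns))
    for (j in use) {
      col <- paste0("dp", j)
      if (!col %in% names(frame)) frame[[col]] <- NA_real_
      frame[[col]][match(rownames(dp$scores), frame$id)] <- dp$scores[, j]
    }
  }
  frame
}

#' Spearman correlation matrix with p-values
#'
#' Rank correlations (average ranks for ties) over pairwise-complete
#' observations, with two-sided p-values from the t approximation.
#' Constant variables yield `NA` cells and are listed in `flagged`.
#'
#' @param frame A data frame; `vars` selects its numeric columns.
#' @param vars Character vector of column names; defaults to all numeric
#'   columns.
#' @return A list: `rho` (symmetric matrix), `p` (matrix), `n` (pairwise
#'   counts), `flagged` (constant variables).
#' @export
spearman_matrix <- function(frame, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(frame)[vapply(frame, is.numeric, logical(1))]
  }
  x <- as.matrix(frame[, vars, drop = FALSE])
  constant <- vars[apply(x, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) < 3 || length(unique(v)) == 1
  })]
  # constant columns are reported via `flagged`; silence cor()'s zero-sd noise
  rho <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs"))
  nmat <- crossprod(!is.na(x))
  tstat <- rho * sqrt((nmat - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = nmat - 2, lower.tail = FALSE)
  diag(p) <- NA
  rho[constant, ] <- NA; rho[, constant] <- NA
  p[constant, ] <- NA; p[, constant] <- NA
  diag(rho)[!(vars %in% constant)] <- 1
  list(rho = rho, p = p, n = nmat, flagged = constant)
}

scale_exposures <- function(frame) {
  frame |>
    dplyr::mutate(
      protein_5g = .data$daily_protein_g / 5,
      breakfast_5g = .data$breakfast / 5,
      lunch_5g = .data$lunch / 5,
      dinner_5g = .data$dinner / 5,
      other_5g = .data$other / 5,
      education = factor(.data$education,
                         levels = c("primary", "secondary", "university"))
    )
}

fit_one_logistic <- function(data, rhs, model_id, terms_of_interest, units,
                             adjustment) {
  if (length(unique(data$meets_cutoff)) < 2) {
    stop("outcome is constant; logistic model '", model_id,
         "' cannot be fitted")
  }
  f <- stats::as.formula(paste("meets_cutoff ~", paste(rhs, collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, family = stats::binomial(), data = data,
               control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) stop("logistic model '", model_id, "' did not converge")
  if (separation) {
    return(tibble::tibble(model = model_id, term = terms_of_interest,
                          unit = units, or = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_, adjustment = adjustment,
                          note = "perfect separation; model skipped"))
  }
  est <- stats::coef(fit)[terms_of_interest]
  se <- sqrt(diag(stats::vcov(fit))[terms_of_interest])
  tibble::tibble(
    model = model_id, term = terms_of_interest, unit = units,
    or = exp(est), ci_lo = exp(est - 1.96 * se), ci_hi = exp(est + 1.96 * se),
    adjustment = adjustment, note = NA_character_
  )
}

#' Logistic models for meeting the protein-adequacy cutoff
#'
#' Fits, within one stratum, the suite of binary logistic regressions with
#' outcome "meets >= 1.1 g protein/kg adjusted body weight":
#'
#' * daily block — daily protein (per 5 g), energy (per MJ) and total EDO
#'   frequency (per 1 EDO), each individually adjusted for age and
#'   education only, and all three mutually adjusted (single model);
#' * meal block — protein at each self-indicated meal (per 5 g),
#'   individually and in one additive model, always adjusted for age,
#'   education, energy and total EDO;
#' * dietary-pattern block — each retained pattern score (per score SD),
#'   individually and jointly, with the same adjustment set.
#'
#' Wald 95% CIs, exp(beta +/- 1.96 SE).  Every estimate carries its
#' adjustment set.  Perfect separation flags and skips the model; an
#' outcome with no variation is an error.
#'
#' @param frame One-sex analysis frame from [build_analysis_frame()].
#' @return A tidy tibble: `model`, `term`, `unit`, `or`, `ci_lo`, `ci_hi`,
#'   `adjustment`, `note`.
#' @export
fit_logistic_suite <- function(frame) {
  d <- scale_exposures(frame)
  d$education <- droplevels(d$education)
  base_adj <- c("age", if (nlevels(d$education) > 1) "education")
  full_adj <- c(base_adj, "energy_mj", "total_edo")
  out <- list()

  daily <- c(protein_5g = "per 5 g/day", energy_mj = "per MJ/day",
             total_edo = "per 1 EDO/day")
  for (v in names(daily)) {
    out[[paste0("daily-individual-", v)]] <- fit_one_logistic(
      d, c(v, base_adj), "daily-individual", v, daily[[v]],
      paste(base_adj, collapse = "+"))
  }
  out[["daily-mutual"]] <- fit_one_logistic(
    d, c(names(daily), base_adj), "daily-mutual", names(daily),
    unname(daily), paste(c(names(daily), base_adj), collapse = "+"))

  meals <- c(breakfast_5g = "per 5 g/meal", lunch_5g = "per 5 g/meal",
             dinner_5g = "per 5 g/meal", other_5g = "per 5 g/meal")
  for (v in names(meals)) {
    out[[paste0("meal-individual-", v)]] <- fit_one_logistic(
      d, c(v, full_adj), "meal-individual", v, meals[[v]],
      paste(full_adj, collapse = "+"))
  }
  out[["meal-mutual"]] <- fit_one_logistic(
    d, c(names(meals), full_adj), "meal-mutual", names(meals),
    unname(meals), paste(c(names(meals), full_adj), collapse = "+"))

  dps <- grep("^dp[0-9]+$", names(d), value = TRUE)
  dps <- dps[vapply(dps, function(v) !all(is.na(d[[v]])), logical(1))]
  if (length(dps)) {
    for (v in dps) {
      out[[paste0("pattern-individual-", v)]] <- fit_one_logistic(
        d, c(v, full_adj), "pattern-individual", v, "per score SD",
        paste(full_adj, collapse = "+"))
    }
    out[["pattern-mutual"]] <- fit_one_logistic(
      d, c(dps, full_adj), "pattern-mutual", dps,
      rep("per score SD", length(dps)),
      paste(c(dps, full_adj), collapse = "+"))
  }
  dplyr::bind_rows(out)
}

#' Assemble report tables from a completed analysis
#'
#' Produces analogues of the study's four table shapes on whatever cohort
#' was supplied: participant characteristics by sex and adequacy, the
#' bolus-attainment table, sex-stratified Spearman matrices, and the
#' logistic-model suite.
#'
#' @param frame Analysis frame from [build_analysis_frame()].
#' @param out_dir Optional directory; when given, tables are written as CSV.
#' @return A list: `characteristics`, `bolus`, `spearman` (per sex),
#'   `models` (per sex).
#' @export
build_report <- function(frame, out_dir = NULL) {
  characteristics <- frame |>
    dplyr::group_by(.data$sex, .data$meets_cutoff) |>
    dplyr::summarise(
      n = dplyr::n(),
      age_mean = mean(.data$age), age_sd = stats::sd(.data$age),
      bmi_mean = mean(.data$bmi), bmi_sd = stats::sd(.data$bmi),
      energy_mj_mean = mean(.data$energy_mj),
      protein_g_mean = mean(.data$daily_protein_g),
      protein_e_pct_mean = mean(.data$protein_e_pct),
      g_per_kg_mean = mean(.data$g_per_kg),
      total_edo_mean = mean(.data$total_edo),
      .groups = "drop"
    )
  bolus <- bolus_table(dplyr::rename(frame, participant_id = "id"))
  corr_vars <- c("energy_mj", "daily_protein_g", "protein_e_pct", "g_per_kg",
                 "breakfast", "lunch", "dinner", "other", "cv",
                 "total_edo", "large_edo", "small_edo",
                 grep("^dp[0-9]+$", names(frame), value = TRUE))
  spearman <- lapply(split(frame, frame$sex), spearman_matrix,
                     vars = intersect(corr_vars, names(frame)))
  models <- frame |>
    dplyr::group_by(.data$sex) |>
    dplyr::group_modify(~ fit_logistic_suite(.x)) |>
    dplyr::ungroup()
  tables <- list(characteristics = characteristics, bolus = bolus,
                 spearman = spearman, models = models)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(characteristics, file.path(out_dir, "table1_characteristics.csv"))
    readr::write_csv(bolus, file.path(out_dir, "table2_bolus.csv"))
    for (sx in names(spearman)) {
      rho <- tibble::as_tibble(spearman[[sx]]$rho, rownames = "variable")
      readr::write_csv(rho, file.path(out_dir, sprintf("table3_spearman_%s.csv", sx)))
    }
    readr::write_csv(models, file.path(out_dir, "table4_models.csv"))
  }
  tables
}
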