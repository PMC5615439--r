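#' Cohort energy-balance summary
#'
#' Descriptive summary of both sides of the energy balance: mean daily
#' energy intake split into macronutrient kcal (from the percentage
#' composition) and mean daily expenditure split into RMR, DIT and PAEE
#' (via [derive_components()]), each with its percent share. Days are
#' averaged within subject first, then across subjects, so unbalanced
#' day counts do not weight subjects unequally.
#'
#' @param records Daily-record tibble (valid-day filtered as desired).
#' @param subjects Subject tibble with `rmr_kcal`.
#' @param dit_fraction Fraction of TEE attributed to DIT; default 0.10.
#' @return Tibble with `side` (intake/expenditure), `component`,
#'   `kcal_mean` and `pct` of that side's total.
#' @export
energy_balance_summary <- function(records, subjects, dit_fraction = 0.10) {
  per_subj <- records |>
    dplyr::inner_join(dplyr::select(subjects, "subject_id", "rmr_kcal"),
                      by = "subject_id") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      tee = mean(.data$tee_kcal, na.rm = TRUE),
      rmr = dplyr::first(.data$rmr_kcal),
      intake = mean(.data$intake_kcal, na.rm = TRUE),
      protein = mean(.data$intake_kcal * .data$protein_pct / 100, na.rm = TRUE),
      fat = mean(.data$intake_kcal * .data$fat_pct / 100, na.rm = TRUE),
      carb = mean(.data$intake_kcal * .data$carb_pct / 100, na.rm = TRUE),
      alcohol = mean(.data$intake_kcal * .data$alcohol_pct / 100, na.rm = TRUE),
      .groups = "drop"
    )
  part <- derive_components(per_subj$tee, per_subj$rmr, dit_fraction)
  exp_means <- c(
    rmr = mean(part$rmr), dit = mean(part$dit), paee = mean(part$paee)
  )
  tee_mean <- mean(part$tee)
  intake_means <- c(
    carbohydrate = mean(per_subj$carb, na.rm = TRUE),
    fat = mean(per_subj$fat, na.rm = TRUE),
    protein = mean(per_subj$protein, na.rm = TRUE),
    alcohol = mean(per_subj$alcohol, na.rm = TRUE)
  )
  intake_mean <- mean(per_subj$intake, na.rm = TRUE)
  dplyr::bind_rows(
    tibble::tibble(
      side = "intake",
      component = c("total", names(intake_means)),
      kcal_mean = c(intake_mean, unname(intake_means)),
      pct = c(100, 100 * unname(intake_means) / intake_mean)
    ),
    tibble::tibble(
      side = "expenditure",
      component = c("total", names(exp_means)),
      kcal_mean = c(tee_mean, unname(exp_means)),
      pct = c(100, 100 * unname(exp_means) / tee_mean)
    )
  )
}

# add 1-decimal display copies of percent columns alongside full precision
.with_display <- function(df, cols) {
  for (col in intersect(cols, names(df))) {
    df[[paste0(col, "_1dp")]] <- round(df[[col]], 1)
  }
  df
}

#' Run the full reporting pipeline
#'
#' Orchestrates every analysis stage on one cohort and writes the output
#' tables: (a) the reliability table (ICC, days needed, CV per outcome),
#' (b) day-of-week adjusted means and pairwise contrasts, (c) a
#' magnitude-based-inference effects table (covariate 2-SD effects,
#' measurement-order effects, highest-lowest day effects), (d) the
#' energy-balance component summary, and (e) a JSON provenance log.
#' Re-running on identical inputs reproduces identical tables.
#'
#' @param records Daily-record tibble (unfiltered; the wear filter is
#'   applied here).
#' @param subjects Subject tibble.
#' @param output_dir Directory for the output files (created if absent).
#' @param outcomes Outcomes to analyse; default those present.
#' @param dow_outcomes Outcomes for the day-of-week table; default the
#'   intensity-band and macronutrient outcomes.
#' @param mbi_covariates Covariates for per-outcome 2-SD / level effects.
#' @param target_icc,wear_cutoff,offsets Passed to [reliability_table()].
#' @return Invisibly, a list with all computed tables and the file paths.
#' @export
run_report <- function(records, subjects, output_dir,
                       outcomes = intersect(default_outcomes(), names(records)),
                       dow_outcomes = intersect(
                         c("sedentary_min", "light_min", "mvpa_min",
                           "protein_pct", "fat_pct", "carb_pct", "alcohol_pct"),
                         outcomes
                       ),
                       mbi_covariates = c("sex", "injury_level", "wear_time", "age"),
                       target_icc = 0.80, wear_cutoff = 0.80,
                       offsets = default_offsets(outcomes)) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  valid <- filter_valid_days(records, cutoff_fraction = wear_cutoff)

  rel <- reliability_table(
    valid, subjects, outcomes = outcomes, target_icc = target_icc,
    offsets = offsets, apply_wear_filter = FALSE
  )
  fits <- reliability_fits(rel)

  mbi_rows <- purrr::map(outcomes, function(oc) {
    fit <- fits[[oc]]
    covs <- intersect(mbi_covariates, fit$covariates)
    rows <- purrr::map(covs, function(cv) covariate_effect(fit, cv))
    if ("order_index" %in% fit$covariates) {
      rows <- c(rows, list(order_effect(fit, n_days = max(valid$order_index))))
    }
    dplyr::bind_rows(rows)
  })
  dow <- purrr::map(dow_outcomes, function(oc) day_of_week_effects(fits[[oc]]))
  names(dow) <- dow_outcomes
  dow_means <- purrr::map_dfr(dow, function(d) {
    dplyr::mutate(d$adjusted_means, outcome = d$outcome, .before = 1)
  })
  dow_contrasts <- purrr::map_dfr(dow, function(d) {
    dplyr::mutate(d$contrasts, outcome = d$outcome, .before = 1)
  })
  mbi <- dplyr::bind_rows(
    dplyr::bind_rows(mbi_rows),
    purrr::map_dfr(dow, function(d) d$highest_lowest)
  )
  balance <- energy_balance_summary(valid, subjects)

  paths <- list(
    reliability = file.path(output_dir, "reliability.csv"),
    day_of_week_means = file.path(output_dir, "day_of_week_means.csv"),
    day_of_week_contrasts = file.path(output_dir, "day_of_week_contrasts.csv"),
    mbi_effects = file.path(output_dir, "mbi_effects.csv"),
    energy_balance = file.path(output_dir, "energy_balance.csv"),
    provenance = file.path(output_dir, "provenance.json")
  )
  readr::write_csv(
    .with_display(tibble::as_tibble(rel), c("cv_mean_pct", "cv_lo95", "cv_hi95")),
    paths$reliability, progress = FALSE
  )
  readr::write_csv(dow_means, paths$day_of_week_means, progress = FALSE)
  readr::write_csv(
    .with_display(dow_contrasts, c("effect_pct", "ci_lo_pct", "ci_hi_pct")),
    paths$day_of_week_contrasts, progress = FALSE
  )
  readr::write_csv(
    .with_display(mbi, c("effect_pct", "ci_lo_pct", "ci_hi_pct")),
    paths$mbi_effects, progress = FALSE
  )
  readr::write_csv(.with_display(balance, "pct"), paths$energy_balance,
                   progress = FALSE)

  provenance <- list(
    package = "ebvar",
    version = as.character(utils::packageVersion("ebvar")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = list(
      outcomes = outcomes, dow_outcomes = dow_outcomes,
      mbi_covariates = mbi_covariates,
      target_icc = target_icc, wear_cutoff = wear_cutoff,
      offsets = as.list(offsets)
    ),
    data = list(
      n_subjects = length(unique(valid$subject_id)),
      n_records_input = nrow(records),
      n_records_valid = nrow(valid)
    ),
    convergence = purrr::map(fits, function(f) {
      msgs <- f$model@optinfo$conv$lme4$messages
      list(
        outcome = f$outcome,
        singular = lme4::isSingular(f$model),
        messages = if (is.null(msgs)) character(0) else msgs
      )
    })
  )
  jsonlite::write_json(provenance, paths$provenance, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    reliability = rel,
    day_of_week = dow,
    mbi_effects = mbi,
    energy_balance = balance,
    valid_records = valid,
    paths = paths
  ))
}
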