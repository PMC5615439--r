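#' Fixed covariates used in the daily-outcome models
#'
#' The adjustment set for the mixed models: subject age (years), ordinal
#' injury-level code, daily wear time (as a fraction of the day), sex,
#' day of the week (categorical) and the linear "day of entry" order index
#' that captures drifts in reporting across the monitoring week.
#'
#' @return Character vector of covariate names.
#' @export
default_covariates <- function() {
  c("age", "injury_level", "wear_time", "sex", "day_of_week", "order_index")
}

# map covariate names to model-frame columns
.covariate_column <- c(
  age = "age",
  injury_level = "injury_level_code",
  wear_time = "wear_fraction",
  sex = "sex",
  day_of_week = "day_of_week",
  order_index = "order_index"
)

# Assemble the analysis frame for one outcome: join subjects, log-transform,
# derive wear fraction, drop rows with a missing outcome.
.prepare_model_data <- function(records, subjects, outcome, offset) {
  if (!outcome %in% names(records)) {
    abort(sprintf("Outcome '%s' not found in the daily table", outcome),
          class = "ebvar_schema_error")
  }
  dat <- dplyr::inner_join(records, subjects, by = "subject_id")
  dat <- dat[!is.na(dat[[outcome]]), , drop = FALSE]
  dat$y_log <- log_transform(dat[[outcome]], offset)
  dat$wear_fraction <- dat$wear_minutes / 1440
  dat$day_of_week <- factor(dat$day_of_week, levels = .day_levels)
  dat$day_of_week <- droplevels(dat$day_of_week)
  dat$sex <- factor(dat$sex, levels = c("female", "male"))
  dat$order_index <- as.numeric(dat$order_index)
  dat
}

#' Fit the random-intercept variance-decomposition model for one outcome
#'
#' Fits, by REML, a linear mixed model to the natural-log of a daily
#' outcome with a subject random intercept and the requested fixed
#' covariates:
#' \deqn{\log(y_{ij} + c) = \beta_0 + x_{ij}'\beta + u_i + e_{ij},}
#' with \eqn{u_i \sim N(0, \sigma^2_b)} between subjects and
#' \eqn{e_{ij} \sim N(0, \sigma^2_w)} within. The between/within variance
#' components feed the intraclass correlation; the fixed-effect
#' coefficients feed the magnitude-based-inference engine.
#'
#' @param records Daily-record tibble (valid-day filtering is the caller's
#'   responsibility; see [filter_valid_days()]).
#' @param subjects Subject tibble (`subject_id`, `age`, `sex`,
#'   `injury_level_code`, `rmr_kcal`).
#' @param outcome Name of the outcome column to model.
#' @param covariates Fixed covariates, a subset of [default_covariates()].
#'   Use `character(0)` for the unadjusted (intercept-only) model that the
#'   one-way ANOVA estimators reproduce on balanced data.
#' @param offset Additive log offset for this outcome (see
#'   [default_offsets()]).
#' @return An object of class `vc_fit`: variance components
#'   (`sigma2_between`, `sigma2_within`), a `fixed` tibble of coefficients
#'   with standard errors, the residual degrees of freedom
#'   (`n_obs - n_fixed - n_subjects`), covariate summaries used for
#'   2-SD effects, and the underlying `lme4` fit in `$model`.
#' @export
fit_variance_model <- function(records, subjects, outcome,
                               covariates = default_covariates(),
                               offset = 0) {
  covariates <- unique(covariates)
  unknown <- setdiff(covariates, names(.covariate_column))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown covariate(s): %s", paste(unknown, collapse = ", ")),
          class = "ebvar_validation_error")
  }
  dat <- .prepare_model_data(records, subjects, outcome, offset)
  n_per_subj <- table(dat$subject_id)
  if (sum(n_per_subj >= 2) < 2) {
    abort("Need at least 2 subjects with at least 2 valid days each",
          class = "ebvar_estimation_error")
  }
  cols <- unname(.covariate_column[covariates])
  for (i in seq_along(covariates)) {
    v <- dat[[cols[i]]]
    if (length(unique(v[!is.na(v)])) < 2) {
      abort(sprintf("Covariate '%s' is constant in the data; singular design",
                    covariates[i]),
            class = "ebvar_estimation_error")
    }
  }
  rhs <- paste(c(cols, "(1 | subject_id)"), collapse = " + ")
  form <- stats::as.formula(paste("y_log ~", rhs))
  fit <- tryCatch(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    error = function(e) {
      abort(sprintf("Mixed-model estimation failed for '%s': %s",
                    outcome, conditionMessage(e)),
            class = "ebvar_estimation_error")
    }
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_between <- vc$vcov[vc$grp == "subject_id"][1]
  sigma2_within <- vc$vcov[vc$grp == "Residual"][1]
  cm <- summary(fit)$coefficients
  fixed <- tibble::tibble(
    term = rownames(cm),
    estimate = unname(cm[, "Estimate"]),
    std_error = unname(cm[, "Std. Error"])
  )
  n_obs <- nrow(dat)
  n_subjects <- length(unique(dat$subject_id))
  df_resid <- max(1, n_obs - nrow(fixed) - n_subjects)
  numeric_cols <- cols[vapply(dat[cols], is.numeric, logical(1))]
  cov_sd <- vapply(dat[numeric_cols], stats::sd, numeric(1), na.rm = TRUE)
  structure(
    list(
      outcome = outcome,
      covariates = covariates,
      offset = offset,
      sigma2_between = sigma2_between,
      sigma2_within = sigma2_within,
      fixed = fixed,
      vcov_fixed = as.matrix(vcov(fit)),
      df_resid = df_resid,
      n_obs = n_obs,
      n_subjects = n_subjects,
      covariate_sd = cov_sd,
      data = dat,
      model = fit
    ),
    class = "vc_fit"
  )
}

#' @exportS3Method base::print
print.vc_fit <- function(x, ...) {
  cat(sprintf("Variance decomposition of log(%s + %g)\n", x$outcome, x$offset))
  cat(sprintf("  %d observations, %d subjects; residual df %d\n",
              x$n_obs, x$n_subjects, x$df_resid))
  cat(sprintf("  sigma^2 between = %.5f, within = %.5f, ICC = %.3f\n",
              x$sigma2_between, x$sigma2_within, icc_from_components(x)))
  if (length(x$covariates) > 0) {
    cat("  fixed covariates:", paste(x$covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a variance-decomposition fit
#'
#' @param x A `vc_fit` object.
#' @param effects `"fixed"` for coefficients, `"ran_pars"` for variance
#'   components, or `"all"`.
#' @param ... Unused.
#' @return A tibble of terms and estimates.
#' @export
tidy.vc_fit <- function(x, effects = c("all", "fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  fixed <- dplyr::mutate(x$fixed, effect = "fixed", .before = 1)
  ran <- tibble::tibble(
    effect = "ran_pars",
    term = c("sigma2_between", "sigma2_within"),
    estimate = c(x$sigma2_between, x$sigma2_within),
    std_error = NA_real_
  )
  out <- switch(effects,
    fixed = fixed,
    ran_pars = ran,
    all = dplyr::bind_rows(fixed, ran)
  )
  out
}

#' One-row summary of a variance-decomposition fit
#'
#' @param x A `vc_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with variance components, ICC and sizes.
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    sigma2_between = x$sigma2_between,
    sigma2_within = x$sigma2_within,
    icc = icc_from_components(x),
    n_obs = x$n_obs,
    n_subjects = x$n_subjects,
    df_resid = x$df_resid
  )
}

#' Intraclass correlation from variance components
#'
#' The single-day reliability of an outcome: the ratio of between-subject
#' variance to total variance, \eqn{\sigma^2_b / (\sigma^2_b + \sigma^2_w)}.
#' A negative between-subject estimate (possible for the moment-based ANOVA
#' estimator) is truncated to 0 before the ratio.
#'
#' @param x Either a `vc_fit` object or the between-subject variance.
#' @param sigma2_within Within-subject (residual) variance, required when
#'   `x` is numeric.
#' @return ICC in \[0, 1\].
#' @export
#' @examples
#' icc_from_components(0.2, 0.6) # 0.25
icc_from_components <- function(x, sigma2_within = NULL) {
  if (inherits(x, "vc_fit")) {
    sigma2_between <- x$sigma2_between
    sigma2_within <- x$sigma2_within
  } else {
    sigma2_between <- x
    if (is.null(sigma2_within)) {
      abort("Provide sigma2_within alongside a numeric sigma2_between",
            class = "ebvar_validation_error")
    }
  }
  sigma2_between <- pmax(sigma2_between, 0)
  if (sigma2_between + sigma2_within <= 0) {
    abort("Total variance is zero; ICC undefined", class = "ebvar_domain_error")
  }
  sigma2_between / (sigma2_between + sigma2_within)
}

#' Spearman-Brown step-up: reliability of an n-day average
#'
#' @param icc_single Single-day ICC in (0, 1).
#' @param n_days Number of averaged days.
#' @return Reliability of the n-day mean,
#'   `n * icc / (1 + (n - 1) * icc)`.
#' @export
spearman_brown_step_up <- function(icc_single, n_days) {
  n_days * icc_single / (1 + (n_days - 1) * icc_single)
}

#' Days of monitoring needed for a target reliability
#'
#' Inverts the Spearman-Brown prophecy formula: the number of days whose
#' average attains reliability `icc_target` given single-day reliability
#' `icc_single` is
#' \deqn{N = \frac{ICC_t}{1 - ICC_t} \cdot \frac{1 - ICC_s}{ICC_s}.}
#' The practical recommendation is the ceiling of N, since days are whole.
#'
#' @param icc_single Single-day ICC, strictly inside (0, 1). Vectorised.
#' @param icc_target Target reliability, strictly inside (0, 1);
#'   default 0.80 (the conventional acceptable-reliability cut-off).
#' @return A tibble with `icc_single`, `icc_target`, `days_needed_real`
#'   (N) and `days_needed` (ceiling of N, at least 1).
#' @export
#' @examples
#' days_needed(c(0.8, 0.5, 0.2)) # 1, 4, 16 days
days_needed <- function(icc_single, icc_target = 0.80) {
  if (any(icc_single <= 0 | icc_single >= 1)) {
    abort("icc_single must lie strictly inside (0, 1)", class = "ebvar_domain_error")
  }
  if (length(icc_target) != 1 || icc_target <= 0 || icc_target >= 1) {
    abort("icc_target must be a single value strictly inside (0, 1)",
          class = "ebvar_domain_error")
  }
  n_real <- (icc_target / (1 - icc_target)) * ((1 - icc_single) / icc_single)
  tibble::tibble(
    icc_single = icc_single,
    icc_target = icc_target,
    days_needed_real = n_real,
    days_needed = pmax(1L, as.integer(ceiling(n_real * (1 - 1e-9))))
  )
}

#' Intra-individual coefficient of variation
#'
#' Day-to-day variability of an outcome within each subject, on the raw
#' (untransformed) scale: per-subject CV = 100 x sample SD across that
#' subject's days / subject mean. The cohort summary is the mean of
#' per-subject CVs with a 95% t-interval across subjects.
#'
#' @param records Daily-record tibble (already valid-day filtered).
#' @param outcome Outcome column name.
#' @param min_days Minimum days with the outcome present for a subject to
#'   contribute; default 2.
#' @return A tibble with one row per contributing subject (`subject_id`,
#'   `n_days`, `cv_pct`) carrying the cohort summary as attributes
#'   `cv_mean_pct` and `cv_ci95`; [summarise_cv()] extracts the summary as
#'   a one-row tibble. Subjects with mean zero are dropped with a warning.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   subject_id = "S01", order_index = 1:3,
#'   day_of_week = c("Mon", "Tue", "Wed"), wear_minutes = 1440,
#'   tee_kcal = c(1, 2, 3)
#' )
#' intra_individual_cv(rec, "tee_kcal") # CV = 50%
intra_individual_cv <- function(records, outcome, min_days = 2) {
  if (!outcome %in% names(records)) {
    abort(sprintf("Outcome '%s' not found", outcome), class = "ebvar_schema_error")
  }
  per <- records |>
    dplyr::filter(!is.na(.data[[outcome]])) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      mean_val = mean(.data[[outcome]]),
      sd_val = sd(.data[[outcome]]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_days >= min_days)
  zero <- per$mean_val == 0
  if (any(zero)) {
    warn(sprintf(
      "Excluding %d subject(s) with zero mean for '%s' (CV undefined)",
      sum(zero), outcome
    ))
    per <- per[!zero, , drop = FALSE]
  }
  per <- dplyr::transmute(
    per,
    subject_id = .data$subject_id,
    n_days = .data$n_days,
    cv_pct = 100 * .data$sd_val / .data$mean_val
  )
  n <- nrow(per)
  if (n == 0) {
    abort(sprintf("No subject has >= %d days with '%s' present", min_days, outcome),
          class = "ebvar_estimation_error")
  }
  m <- mean(per$cv_pct)
  half <- if (n > 1) qt(0.975, n - 1) * sd(per$cv_pct) / sqrt(n) else NA_real_
  attr(per, "outcome") <- outcome
  attr(per, "cv_mean_pct") <- m
  attr(per, "cv_ci95") <- c(m - half, m + half)
  per
}

#' Cohort CV summary
#'
#' @param per_subject_cv Output of [intra_individual_cv()].
#' @return One-row tibble: `outcome`, `n_subjects`, `cv_mean_pct`,
#'   `cv_lo95`, `cv_hi95`.
#' @export
summarise_cv <- function(per_subject_cv) {
  ci <- attr(per_subject_cv, "cv_ci95")
  tibble::tibble(
    outcome = attr(per_subject_cv, "outcome"),
    n_subjects = nrow(per_subject_cv),
    cv_mean_pct = attr(per_subject_cv, "cv_mean_pct"),
    cv_lo95 = ci[1],
    cv_hi95 = ci[2]
  )
}

#' Reliability table across outcomes
#'
#' Runs the full reliability pipeline for each outcome: mixed-model
#' variance decomposition of the log outcome, single-day ICC,
#' Spearman-Brown days needed for the target reliability, and
#' intra-individual CV — one row per outcome. Rows whose prophecy
#' extrapolation exceeds the longest observed monitoring run are flagged
#' `beyond_observed` (extrapolation loses precision past the measured
#' window); outcomes with no detectable between-subject variance are
#' flagged `unreliable` with missing days-needed.
#'
#' @param records Daily-record tibble. Valid-day filtering is applied
#'   first when `apply_wear_filter = TRUE`.
#' @param subjects Subject tibble.
#' @param outcomes Outcome columns to analyse; defaults to those present.
#' @param covariates Fixed covariates for the models
#'   (see [default_covariates()]).
#' @param target_icc Target reliability; default 0.80.
#' @param offsets Named log-offset vector (see [default_offsets()]).
#' @param apply_wear_filter Apply [filter_valid_days()] first? Default TRUE.
#' @param wear_cutoff Cutoff fraction for the wear filter.
#' @return A tibble of class `reliability_table`, one row per outcome, with
#'   the per-outcome model fits in the `"fits"` attribute.
#' @export
reliability_table <- function(records, subjects,
                              outcomes = intersect(default_outcomes(), names(records)),
                              covariates = default_covariates(),
                              target_icc = 0.80,
                              offsets = default_offsets(outcomes),
                              apply_wear_filter = TRUE,
                              wear_cutoff = 0.80) {
  if (apply_wear_filter) {
    records <- filter_valid_days(records, cutoff_fraction = wear_cutoff)
  }
  fits <- list()
  rows <- purrr::map(outcomes, function(oc) {
    off <- if (oc %in% names(offsets)) offsets[[oc]] else 0
    fit <- fit_variance_model(records, subjects, oc,
                              covariates = covariates, offset = off)
    fits[[oc]] <<- fit
    icc <- icc_from_components(fit)
    dn <- tryCatch(
      days_needed(icc, icc_target = target_icc),
      error = function(e) tibble::tibble(
        icc_single = icc, icc_target = target_icc,
        days_needed_real = NA_real_, days_needed = NA_integer_
      )
    )
    cv <- summarise_cv(intra_individual_cv(records, oc))
    max_days <- max(table(fit$data$subject_id))
    tibble::tibble(
      outcome = oc,
      n_subjects = fit$n_subjects,
      n_obs = fit$n_obs,
      icc_single_day = icc,
      days_needed_real = dn$days_needed_real,
      days_needed = dn$days_needed,
      cv_mean_pct = cv$cv_mean_pct,
      cv_lo95 = cv$cv_lo95,
      cv_hi95 = cv$cv_hi95,
      beyond_observed = !is.na(dn$days_needed) & dn$days_needed > max_days,
      unreliable = is.na(dn$days_needed)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  attr(out, "target_icc") <- target_icc
  class(out) <- c("reliability_table", class(out))
  out
}

#' Model fits underlying a reliability table
#'
#' @param x A `reliability_table`.
#' @return Named list of `vc_fit` objects, one per outcome.
#' @export
reliability_fits <- function(x) attr(x, "fits")
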