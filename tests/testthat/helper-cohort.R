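# Small in-code fixtures shared across test files.

# Minimal subject table.
make_subjects <- function(n = 5, seed = 11) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    age = round(runif(n, 25, 60), 1),
    sex = rep_len(c("male", "female"), n),
    injury_level = sample(c("T4", "T7", "T10", "L1"), n, replace = TRUE),
    rmr_kcal = round(runif(n, 1200, 1800))
  ) |>
    dplyr::mutate(injury_level_code = parse_injury_level(injury_level))
}

# Balanced daily grid with a lognormal outcome: subject intercepts u_i,
# within-day noise e_ij. Returns full-wear days so no filtering applies.
make_balanced_records <- function(n_subjects = 5, n_days = 4,
                                  sigma_b = 0.2, sigma_w = 0.1,
                                  mu = 7, seed = 7, outcome = "tee_kcal") {
  set.seed(seed)
  u <- rnorm(n_subjects, 0, sigma_b)
  recs <- tidyr::expand_grid(
    subject = seq_len(n_subjects),
    order_index = seq_len(n_days)
  )
  recs$subject_id <- sprintf("S%02d", recs$subject)
  recs$day_of_week <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[
    ((recs$order_index - 1) %% 7) + 1
  ]
  recs$wear_minutes <- 1440
  recs[[outcome]] <- exp(mu + u[recs$subject] + rnorm(nrow(recs), 0, sigma_w))
  recs$subject <- NULL
  recs
}

# One-way ANOVA closed-form variance components for a balanced grid:
# the independent oracle for the REML fit. k = days per subject.
anova_components <- function(y_log, subject) {
  k <- unname(table(subject))[1]
  stopifnot(all(table(subject) == k))
  grand <- mean(y_log)
  means <- tapply(y_log, subject, mean)
  n_subj <- length(means)
  ms_between <- k * sum((means - grand)^2) / (n_subj - 1)
  ms_within <- sum((y_log - means[as.character(subject)])^2) /
    (length(y_log) - n_subj)
  list(
    sigma2_within = ms_within,
    sigma2_between = (ms_between - ms_within) / k
  )
}

# A tiny generator config with one configurable outcome.
one_outcome_config <- function(n_subjects, n_days = 7,
                               sigma_b = 0.3, sigma_w = 0.3,
                               mu = 7, outcome = "tee_kcal",
                               order_drift_pct = 0, ...) {
  generator_config(
    n_subjects = n_subjects, n_days = n_days,
    outcomes = tibble::tibble(
      outcome = outcome, mu_log = mu,
      sigma_between = sigma_b, sigma_within = sigma_w,
      order_drift_pct = order_drift_pct
    ),
    low_wear_prob = 0, missing_day_prob = 0,
    ...
  )
}
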