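#' Configure the synthetic cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. Each outcome
#' follows a lognormal daily model
#' \deqn{\log y_{ij} = \mu + x_i'\gamma + d_{dow(j)} + \delta (j - 1)
#'   + u_i + e_{ij},}
#' with subject random intercepts \eqn{u_i \sim N(0, \sigma_b^2)}, daily
#' noise \eqn{e_{ij} \sim N(0, \sigma_w^2)}, optional log-scale covariate
#' effects (sex, age, injury-level code, daily wear fraction — all numeric
#' covariates centred so \eqn{\mu} stays the grand log mean), seven
#' day-of-week offsets, and a linear order drift
#' \eqn{\delta = \log(1 + drift/100) / (n_{days} - 1)} reaching the stated
#' total percent change by the last day.
#'
#' @param n_subjects Cohort size (>= 2).
#' @param n_days Monitoring days per subject; default 7.
#' @param outcomes Tibble with one row per outcome: `outcome`, `mu_log`,
#'   `sigma_between`, `sigma_within`, and optionally `order_drift_pct`
#'   (total percent change day 1 to day `n_days`; default 0).
#' @param covariate_effects Optional tibble `outcome` x (`sex_male`,
#'   `age`, `injury_level`, `wear_fraction`) of log-scale slopes;
#'   unlisted outcomes get zeros.
#' @param dow_effects Optional named list: per outcome a length-7 numeric
#'   vector of log-scale offsets (Mon..Sun); unlisted outcomes get zeros.
#' @param sex_female_prob Probability a subject is female; default 0.18.
#' @param age_mean,age_sd,age_range Age distribution (normal, truncated to
#'   the range); defaults 44, 9, \[22, 61\] years.
#' @param injury_code_range Integer range the ordinal injury-level code is
#'   drawn from uniformly; default 8:23 (thoracic T1 through lumbar L4).
#' @param rmr_mean,rmr_sd Measured resting metabolic rate distribution,
#'   kcal/day; defaults 1481 and 180.
#' @param wear_mean_fraction,wear_sd_fraction Daily wear time model on
#'   full-wear days; defaults 0.96 and 0.03 of the day.
#' @param low_wear_prob Probability a day is a low-wear day (fraction
#'   drawn uniformly from `low_wear_range`, typically failing the 80%
#'   validity cutoff); default 0.12.
#' @param low_wear_range Range of the low-wear fraction; default
#'   \[0.40, 0.80\].
#' @param missing_day_prob Probability a day is absent entirely;
#'   default 0.02.
#' @param epoch_band_minutes Expected worn minutes per intensity band for
#'   [generate_epoch_stream()], named `sedentary`, `light`, `mvpa`.
#' @param epoch_wear_fraction Wear fraction for epoch streams; defaults to
#'   `sum(epoch_band_minutes) / 1440` so the configured band minutes are
#'   realised in expectation.
#' @return A validated list of class `generator_config`. The per-outcome
#'   implied single-day ICC \eqn{\sigma_b^2/(\sigma_b^2+\sigma_w^2)} is
#'   available via [implied_icc()].
#' @export
generator_config <- function(n_subjects = 33,
                             n_days = 7,
                             outcomes,
                             covariate_effects = NULL,
                             dow_effects = NULL,
                             sex_female_prob = 0.18,
                             age_mean = 44, age_sd = 9, age_range = c(22, 61),
                             injury_code_range = c(8L, 23L),
                             rmr_mean = 1481, rmr_sd = 180,
                             wear_mean_fraction = 0.96, wear_sd_fraction = 0.03,
                             low_wear_prob = 0.12, low_wear_range = c(0.40, 0.80),
                             missing_day_prob = 0.02,
                             epoch_band_minutes = c(sedentary = 1255, light = 172, mvpa = 12),
                             epoch_wear_fraction = NULL) {
  stopifnot(is.data.frame(outcomes),
            all(c("outcome", "mu_log", "sigma_between", "sigma_within") %in%
                  names(outcomes)))
  if (n_subjects < 2) abort("n_subjects must be >= 2", class = "ebvar_validation_error")
  if (n_days < 1) abort("n_days must be >= 1", class = "ebvar_validation_error")
  if (any(outcomes$sigma_between < 0) || any(outcomes$sigma_within <= 0)) {
    abort("sigma_between must be >= 0 and sigma_within > 0",
          class = "ebvar_validation_error")
  }
  probs <- c(sex_female_prob, low_wear_prob, missing_day_prob)
  if (any(probs < 0 | probs > 1)) {
    abort("Probabilities must lie in [0, 1]", class = "ebvar_validation_error")
  }
  outcomes <- tibble::as_tibble(outcomes)
  if (!"order_drift_pct" %in% names(outcomes)) outcomes$order_drift_pct <- 0
  outcomes$order_drift_pct[is.na(outcomes$order_drift_pct)] <- 0

  eff_cols <- c("sex_male", "age", "injury_level", "wear_fraction")
  eff <- tibble::tibble(outcome = outcomes$outcome)
  for (col in eff_cols) eff[[col]] <- 0
  if (!is.null(covariate_effects)) {
    stopifnot(is.data.frame(covariate_effects), "outcome" %in% names(covariate_effects))
    for (col in intersect(eff_cols, names(covariate_effects))) {
      idx <- match(covariate_effects$outcome, eff$outcome)
      eff[[col]][idx[!is.na(idx)]] <- covariate_effects[[col]][!is.na(idx)]
    }
  }
  dow <- lapply(outcomes$outcome, function(o) {
    v <- if (!is.null(dow_effects) && o %in% names(dow_effects)) {
      dow_effects[[o]]
    } else {
      rep(0, 7)
    }
    if (length(v) != 7) {
      abort(sprintf("dow_effects for '%s' must have length 7", o),
            class = "ebvar_validation_error")
    }
    setNames(v, .day_levels)
  })
  names(dow) <- outcomes$outcome
  if (is.null(epoch_wear_fraction)) {
    epoch_wear_fraction <- min(1, sum(epoch_band_minutes) / 1440)
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_days = as.integer(n_days),
      outcomes = outcomes, covariate_effects = eff, dow_effects = dow,
      sex_female_prob = sex_female_prob,
      age_mean = age_mean, age_sd = age_sd, age_range = age_range,
      injury_code_range = as.integer(injury_code_range),
      rmr_mean = rmr_mean, rmr_sd = rmr_sd,
      wear_mean_fraction = wear_mean_fraction,
      wear_sd_fraction = wear_sd_fraction,
      low_wear_prob = low_wear_prob, low_wear_range = low_wear_range,
      missing_day_prob = missing_day_prob,
      epoch_band_minutes = epoch_band_minutes,
      epoch_wear_fraction = epoch_wear_fraction
    ),
    class = "generator_config"
  )
}

#' Implied single-day ICC of each configured outcome
#'
#' @param config A `generator_config`.
#' @return Tibble with `outcome` and `icc_single_day` implied by the
#'   configured variance components.
#' @export
implied_icc <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  oc <- config$outcomes
  tibble::tibble(
    outcome = oc$outcome,
    icc_single_day = oc$sigma_between^2 /
      (oc$sigma_between^2 + oc$sigma_within^2)
  )
}

#' @exportS3Method base::print
print.generator_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d subjects x %d days, %d outcomes\n",
              x$n_subjects, x$n_days, nrow(x$outcomes)))
  print(dplyr::left_join(
    dplyr::select(x$outcomes, "outcome", "mu_log", "sigma_between", "sigma_within"),
    implied_icc(x), by = "outcome"
  ))
  invisible(x)
}

.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws a subject table and a daily-record table with the statistical
#' structure the reliability analysis assumes (see [generator_config()]).
#' One `set.seed(seed)` call governs every random stream; given the same
#' config and seed the output is identical. Each subject's monitoring week
#' starts on a random weekday and runs consecutively. Intensity-band
#' minutes are rescaled proportionally on the rare days their independent
#' draws exceed the day's wear minutes, and macronutrient percentages are
#' renormalised to sum to 100 when all four are configured.
#'
#' @param config A `generator_config`.
#' @param seed Integer seed.
#' @return A list with `subjects` (subject tibble, including
#'   `injury_level` labels and `injury_level_code`) and `records`
#'   (daily-record tibble, validity-unfiltered).
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(as.integer(seed))
  n <- config$n_subjects
  codes <- injury_level_codes()
  code_lo <- config$injury_code_range[1]; code_hi <- config$injury_code_range[2]
  subjects <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = round(.rtruncnorm(n, config$age_mean, config$age_sd,
                            config$age_range[1], config$age_range[2]), 1),
    sex = ifelse(runif(n) < config$sex_female_prob, "female", "male"),
    injury_level_code = sample(seq(code_lo, code_hi), n, replace = TRUE),
    rmr_kcal = round(pmax(800, rnorm(n, config$rmr_mean, config$rmr_sd)), 0)
  )
  subjects$injury_level <- codes$level[subjects$injury_level_code]
  subjects <- subjects[, c("subject_id", "age", "sex", "injury_level",
                           "injury_level_code", "rmr_kcal")]

  oc <- config$outcomes
  n_out <- nrow(oc)
  # subject random intercepts, one column per outcome
  u <- matrix(rnorm(n * n_out, 0, rep(oc$sigma_between, each = n)),
              nrow = n, dimnames = list(NULL, oc$outcome))

  start_day <- sample.int(7, n, replace = TRUE)
  eff <- config$covariate_effects
  # centred covariate values (so mu_log stays the grand log mean)
  x_sex <- as.numeric(subjects$sex == "male")
  x_sex <- x_sex - mean(x_sex)
  x_age <- subjects$age - mean(subjects$age)
  x_inj <- subjects$injury_level_code - mean(subjects$injury_level_code)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    days <- seq_len(config$n_days)
    keep <- runif(length(days)) >= config$missing_day_prob
    days <- days[keep]
    if (length(days) == 0) days <- 1L
    dow <- .day_levels[((start_day[i] - 1 + days - 1) %% 7) + 1]
    nd <- length(days)
    low <- runif(nd) < config$low_wear_prob
    wf <- ifelse(
      low,
      runif(nd, config$low_wear_range[1], config$low_wear_range[2]),
      pmin(1, rnorm(nd, config$wear_mean_fraction, config$wear_sd_fraction))
    )
    wear_minutes <- round(wf * 1440)
    x_wf <- wf - config$wear_mean_fraction
    day_tbl <- tibble::tibble(
      subject_id = subjects$subject_id[i],
      order_index = as.integer(days),
      day_of_week = dow,
      wear_minutes = wear_minutes
    )
    for (k in seq_len(n_out)) {
      o <- oc$outcome[k]
      delta <- if (config$n_days > 1) {
        log(1 + oc$order_drift_pct[k] / 100) / (config$n_days - 1)
      } else 0
      mu_ij <- oc$mu_log[k] +
        eff$sex_male[k] * x_sex[i] +
        eff$age[k] * x_age[i] +
        eff$injury_level[k] * x_inj[i] +
        eff$wear_fraction[k] * x_wf +
        config$dow_effects[[o]][dow] +
        delta * (days - 1) +
        u[i, k]
      day_tbl[[o]] <- unname(exp(mu_ij + rnorm(nd, 0, oc$sigma_within[k])))
    }
    rows[[i]] <- day_tbl
  }
  records <- dplyr::bind_rows(rows)

  bands <- c("sedentary_min", "light_min", "mvpa_min")
  if (all(bands %in% names(records))) {
    tot <- rowSums(records[bands])
    over <- tot > records$wear_minutes
    scale <- ifelse(over, records$wear_minutes / tot, 1)
    for (b in bands) records[[b]] <- records[[b]] * scale
  }
  macro <- c("protein_pct", "fat_pct", "carb_pct", "alcohol_pct")
  if (all(macro %in% names(records))) {
    tot <- rowSums(records[macro])
    for (m in macro) records[[m]] <- 100 * records[[m]] / tot
  }
  validate_daily_records(records)
  list(subjects = subjects, records = records)
}

#' Generate a one-day minute-epoch MET stream
#'
#' 1440 one-minute epochs for one subject-day. Worn minutes (the
#' configured wear fraction of the day, removed as a single contiguous
#' off-body block) are assigned to intensity bands by a multinomial draw
#' proportional to the configured expected band minutes, with MET values
#' drawn uniformly inside each band (sedentary 0.9-1.5, light 1.5-3.0,
#' MVPA 3.0-6.0).
#'
#' @param config A `generator_config` (uses `epoch_band_minutes` and
#'   `epoch_wear_fraction`).
#' @param date Calendar date of the day.
#' @param subject_id Subject key; default `"S001"`.
#' @param seed Integer seed.
#' @return Tibble of 1440 epochs: `subject_id`, `timestamp`, `met`,
#'   `worn`.
#' @export
generate_epoch_stream <- function(config, date = as.Date("2017-01-02"),
                                  subject_id = "S001", seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(as.integer(seed))
  n_worn <- round(config$epoch_wear_fraction * 1440)
  worn <- rep(TRUE, 1440)
  if (n_worn < 1440) {
    off_start <- sample.int(1440 - (1440 - n_worn) + 1, 1)
    worn[seq(off_start, length.out = 1440 - n_worn)] <- FALSE
  }
  p <- config$epoch_band_minutes / sum(config$epoch_band_minutes)
  band <- sample(c("sedentary", "light", "mvpa"), n_worn, replace = TRUE, prob = p)
  met <- numeric(1440)
  met[worn] <- dplyr::case_match(
    band,
    "sedentary" ~ runif(n_worn, 0.9, 1.5),
    "light" ~ runif(n_worn, 1.5, 3.0),
    "mvpa" ~ runif(n_worn, 3.0, 6.0)
  )
  tibble::tibble(
    subject_id = subject_id,
    timestamp = as.POSIXct(date, tz = "UTC") + 60 * (seq_len(1440) - 1),
    met = met,
    worn = worn
  )
}

#' Cohort configuration emulating a 7-day paraplegia monitoring study
#'
#' A shipped configuration for a cohort of 33 community-dwelling adults
#' with chronic paraplegia monitored for 7 consecutive days: 82% male,
#' age ~ N(44, 9) truncated to 22-61 years, thoracic/upper-lumbar lesion
#' levels, measured RMR around 1481 kcal/day, ~96% daily wear with
#' occasional low-wear and missing days. Per-outcome within-subject SDs
#' are calibrated from published intra-individual CV magnitudes via the
#' exact lognormal identity \eqn{CV = \sqrt{e^{\sigma_w^2} - 1}} (TEE ~7%,
#' PAEE ~34%, MVPA ~97%, intake ~26%, alcohol ~160%, ...), between-subject
#' SDs set so the implied single-day ICCs span the observed ordering (TEE
#' most reliable, dietary fat least), a -15% week-long reporting drift in
#' energy intake, higher alcohol on Friday/Saturday, and modest sex and
#' injury-level effects on the expenditure outcomes. Values are
#' approximate calibrations from summary statistics, not a reproduction
#' of any real cohort.
#'
#' @return A `generator_config`.
#' @export
#' @examples
#' cfg <- preset_paperlike()
#' implied_icc(cfg)
preset_paperlike <- function() {
  cv_to_sigma <- function(cv_pct) sqrt(log(1 + (cv_pct / 100)^2))
  icc_ratio <- function(icc) sqrt(icc / (1 - icc))
  # (outcome, raw mean, within CV %, implied single-day ICC)
  spec <- tibble::tribble(
    ~outcome,        ~mean_raw, ~cv_pct, ~icc,
    "tee_kcal",         2103,      7,    0.850,
    "paee_kcal",         411,     34,    0.727,
    "pal",              1.40,      7,    0.615,
    "sedentary_min",    1150,      9,    0.533,
    "light_min",         172,     46,    0.727,
    "mvpa_min",           12,     97,    0.727,
    "intake_kcal",      1742,     26,    0.533,
    "protein_pct",      19.0,     26,    0.348,
    "fat_pct",          34.4,     26,    0.148,
    "carb_pct",         44.0,     20,    0.296,
    "alcohol_pct",       2.7,    160,    0.320
  )
  sw <- cv_to_sigma(spec$cv_pct)
  sb <- sw * icc_ratio(spec$icc)
  outcomes <- tibble::tibble(
    outcome = spec$outcome,
    mu_log = log(spec$mean_raw) - (sb^2 + sw^2) / 2,
    sigma_between = sb,
    sigma_within = sw,
    order_drift_pct = ifelse(spec$outcome == "intake_kcal", -15, 0)
  )
  # 2-SD injury-level effects sized to observed magnitudes (TEE +12%,
  # PAL +6%, MVPA +95%, sedentary -8% per 2 SD of the code)
  sd_inj <- sqrt((16^2 - 1) / 12) # SD of a discrete uniform on 16 codes
  inj <- function(pct2sd) log(1 + pct2sd / 100) / (2 * sd_inj)
  covariate_effects <- tibble::tribble(
    ~outcome,        ~sex_male, ~injury_level,
    "tee_kcal",      log(1.15),  inj(12),
    "paee_kcal",     log(1.50),  inj(20),
    "pal",           log(1.12),  inj(6),
    "sedentary_min", log(0.96),  inj(-8),
    "light_min",     log(1.40),  inj(10),
    "mvpa_min",      log(2.00),  inj(95),
    "intake_kcal",   log(1.15),  0
  )
  # Friday/Saturday alcohol bump; small weekday structure elsewhere
  dow_effects <- list(
    alcohol_pct = c(-0.29, 0.04, -0.78, -0.35, 0.71, 0.71, -0.04),
    protein_pct = c(0.03, -0.02, -0.05, 0.08, -0.08, -0.02, 0.02),
    light_min = c(-0.07, 0.05, -0.05, -0.10, 0.09, 0.02, 0.06),
    sedentary_min = c(0.015, -0.012, 0.010, 0.012, -0.015, -0.008, -0.002)
  )
  generator_config(
    n_subjects = 33, n_days = 7,
    outcomes = outcomes,
    covariate_effects = covariate_effects,
    dow_effects = dow_effects
  )
}
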