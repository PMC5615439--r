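#' Smallest worthwhile effect on the log scale
#'
#' The threshold separating trivial from substantial effects: a
#' standardised difference in means of 0.20, i.e. 0.20 times the
#' between-subject SD of the log outcome.
#'
#' @param sigma_between_log Between-subject SD on the log scale (> 0).
#' @param standardised_threshold Standardised-difference threshold;
#'   default 0.20.
#' @return The smallest worthwhile effect on the log scale.
#' @export
#' @examples
#' smallest_worthwhile_effect(0.10) # 0.02
smallest_worthwhile_effect <- function(sigma_between_log, standardised_threshold = 0.20) {
  if (any(sigma_between_log <= 0)) {
    abort("sigma_between_log must be positive", class = "ebvar_domain_error")
  }
  standardised_threshold * sigma_between_log
}

#' Probabilities that a true effect is substantially positive, trivial or
#' negative
#'
#' Given a log-scale effect estimate `b` with standard error `se` and
#' residual degrees of freedom, and the smallest-worthwhile-effect
#' threshold `swe`, computes under the central t distribution:
#' `p_positive = P(T > (swe - b)/se)`, `p_negative = P(T < (-swe - b)/se)`,
#' `p_trivial = 1 - p_positive - p_negative`.
#'
#' @param effect_log Effect estimate on the log scale.
#' @param se_log Standard error (> 0).
#' @param df Residual degrees of freedom (>= 1).
#' @param swe_log Smallest worthwhile effect on the log scale (>= 0).
#' @return A tibble with `p_positive`, `p_trivial`, `p_negative`
#'   (each row sums to 1).
#' @export
#' @examples
#' substantiality_probabilities(0.04, 0.01, 30, 0.02) # p_positive ~ 0.97
substantiality_probabilities <- function(effect_log, se_log, df, swe_log) {
  if (any(se_log <= 0)) abort("se_log must be positive", class = "ebvar_domain_error")
  if (any(df < 1)) abort("df must be >= 1", class = "ebvar_domain_error")
  p_pos <- unname(pt((effect_log - swe_log) / se_log, df))
  p_neg <- unname(pt((-swe_log - effect_log) / se_log, df))
  tibble::tibble(
    p_positive = p_pos,
    p_trivial = pmax(0, 1 - p_pos - p_neg),
    p_negative = p_neg
  )
}

.mbi_qualifiers <- tibble::tibble(
  lower = c(-Inf, 0.005, 0.05, 0.25, 0.75, 0.95, 0.995),
  label = c(
    "most unlikely", "very unlikely", "unlikely", "possible",
    "likely", "very likely", "most likely"
  )
)

# probability -> probabilistic qualifier; boundaries go to the higher bin
# (findInterval with closed left endpoints: p = 0.75 maps to "likely")
.qualifier_for <- function(p) {
  .mbi_qualifiers$label[findInterval(p, .mbi_qualifiers$lower)]
}

#' Classify an effect from its substantiality probabilities
#'
#' An effect is *unclear* when the probabilities of crossing the positive
#' and the negative smallest-worthwhile-effect threshold are both greater
#' than 5%. Otherwise it is *clear*: its direction is the most probable
#' category (substantial increase, trivial, substantial decrease; ties
#' broken toward trivial) and the probability of that category is mapped to
#' a probabilistic qualifier: <0.5% most unlikely, 0.5-5% very unlikely,
#' 5-25% unlikely, 25-75% possible, 75-95% likely, 95-99.5% very likely,
#' >99.5% most likely (boundary values fall in the higher bin).
#'
#' @param p_positive,p_trivial,p_negative Category probabilities, summing
#'   to 1 (vectors allowed; or pass the tibble from
#'   [substantiality_probabilities()] as `p_positive`).
#' @return A tibble with `clarity` (`"clear"`/`"unclear"`), `direction`
#'   (`"increase"`/`"trivial"`/`"decrease"`) and `qualifier`.
#' @export
#' @examples
#' classify_effect(0.20, 0.70, 0.10)  # unclear
#' classify_effect(0.998, 0.002, 0)   # most likely increase
classify_effect <- function(p_positive, p_trivial = NULL, p_negative = NULL) {
  if (is.data.frame(p_positive)) {
    pr <- p_positive
    p_positive <- pr$p_positive
    p_trivial <- pr$p_trivial
    p_negative <- pr$p_negative
  }
  p_positive <- unname(p_positive)
  p_trivial <- unname(p_trivial)
  p_negative <- unname(p_negative)
  stopifnot(length(p_positive) == length(p_trivial),
            length(p_trivial) == length(p_negative))
  if (any(abs(p_positive + p_trivial + p_negative - 1) > 1e-6)) {
    abort("Probabilities must sum to 1", class = "ebvar_validation_error")
  }
  n <- length(p_positive)
  clarity <- ifelse(p_positive > 0.05 & p_negative > 0.05, "unclear", "clear")
  direction <- character(n)
  qualifier <- character(n)
  for (i in seq_len(n)) {
    probs <- c(increase = p_positive[i], trivial = p_trivial[i],
               decrease = p_negative[i])
    top <- max(probs)
    # ties broken toward the trivial category
    dir <- if (probs[["trivial"]] >= top) "trivial" else names(probs)[which.max(probs)]
    direction[i] <- dir
    qualifier[i] <- .qualifier_for(probs[[dir]])
  }
  tibble::tibble(clarity = clarity, direction = direction, qualifier = qualifier)
}

# Assemble one MBIEffect row from a log-scale estimate.
.mbi_effect_row <- function(label, effect_log, se_log, df, swe_log,
                            conf_level = 0.95) {
  effect_log <- unname(effect_log)
  se_log <- unname(se_log)
  probs <- substantiality_probabilities(effect_log, se_log, df, swe_log)
  cls <- classify_effect(probs)
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  tibble::tibble(
    label = label,
    effect_log = effect_log,
    se_log = se_log,
    df = df,
    effect_pct = pct_from_log(effect_log),
    ci_lo_pct = pct_from_log(effect_log - tcrit * se_log),
    ci_hi_pct = pct_from_log(effect_log + tcrit * se_log),
    swe_log = swe_log,
    probs,
    cls
  )
}

# Look up a fixed-effect coefficient row by model-matrix term name(s).
.fixed_terms <- function(fit, pattern) {
  fit$fixed[grepl(pattern, fit$fixed$term), , drop = FALSE]
}

#' Magnitude-based inference for a model covariate
#'
#' For a numeric covariate, evaluates the change associated with moving
#' from a "typically low" (1 SD below the mean) to a "typically high"
#' (1 SD above) value — a 2-SD increase, `effect_log = 2 * SD_x * beta` —
#' so magnitudes are comparable across covariates regardless of units. For
#' a binary categorical covariate (sex), the level difference `beta` is
#' used directly. The effect is back-transformed to a percent change and
#' classified against the smallest worthwhile effect derived from the
#' model's between-subject SD.
#'
#' @param fit A `vc_fit` from [fit_variance_model()].
#' @param covariate One of the fitted covariates (e.g. `"injury_level"`,
#'   `"wear_time"`, `"age"`, `"sex"`).
#' @param conf_level Confidence level for the percent CI; default 0.95.
#' @return A one-row MBI-effect tibble (see [classify_effect()] for the
#'   classification fields).
#' @export
covariate_effect <- function(fit, covariate, conf_level = 0.95) {
  stopifnot(inherits(fit, "vc_fit"))
  if (!covariate %in% fit$covariates) {
    abort(sprintf("Covariate '%s' was not in the fitted model", covariate),
          class = "ebvar_validation_error")
  }
  swe <- smallest_worthwhile_effect(sqrt(pmax(fit$sigma2_between, 1e-12)))
  col <- .covariate_column[[covariate]]
  if (covariate == "sex") {
    row <- .fixed_terms(fit, "^sexmale$")
    if (nrow(row) != 1) {
      abort("Sex coefficient not found in the model", class = "ebvar_estimation_error")
    }
    return(.mbi_effect_row(
      sprintf("%s: sex male-female", fit$outcome),
      row$estimate, row$std_error, fit$df_resid, swe, conf_level
    ))
  }
  row <- fit$fixed[fit$fixed$term == col, , drop = FALSE]
  if (nrow(row) != 1) {
    abort(sprintf("Coefficient for '%s' not found in the model", covariate),
          class = "ebvar_estimation_error")
  }
  sd_x <- fit$covariate_sd[[col]]
  .mbi_effect_row(
    sprintf("%s: 2 SD %s", fit$outcome, covariate),
    2 * sd_x * row$estimate, 2 * sd_x * row$std_error,
    fit$df_resid, swe, conf_level
  )
}

#' Measurement-order effect across the monitoring week
#'
#' The linear "day of entry" drift accumulated from day 1 to day
#' `n_days`: `effect_log = (n_days - 1) * beta_order`, back-transformed to
#' the percent change across the week (e.g. drifting energy-intake
#' reporting as diary burden accumulates).
#'
#' @param fit A `vc_fit` with `order_index` among its covariates.
#' @param n_days Length of the monitoring window; default 7.
#' @param conf_level Confidence level; default 0.95.
#' @return A one-row MBI-effect tibble.
#' @export
order_effect <- function(fit, n_days = 7, conf_level = 0.95) {
  stopifnot(inherits(fit, "vc_fit"))
  if (!"order_index" %in% fit$covariates) {
    abort("order_index was not fitted as a covariate", class = "ebvar_validation_error")
  }
  row <- fit$fixed[fit$fixed$term == "order_index", , drop = FALSE]
  swe <- smallest_worthwhile_effect(sqrt(pmax(fit$sigma2_between, 1e-12)))
  .mbi_effect_row(
    sprintf("%s: order day1 to day%d", fit$outcome, n_days),
    (n_days - 1) * row$estimate, (n_days - 1) * row$std_error,
    fit$df_resid, swe, conf_level
  )
}

#' Day-of-week adjusted means, pairwise contrasts and the
#' highest-lowest-day effect
#'
#' From a fit with `day_of_week` as a categorical fixed effect: adjusted
#' means per day are model predictions at the covariate means (reference
#' sex averaged over its levels), back-transformed to the raw scale with
#' t-based 95% CIs; all 21 pairwise day contrasts are reported with
#' unadjusted p-values (optionally Holm-corrected); and the
#' highest-versus-lowest fitted day is back-transformed to a percent
#' effect with CI and a magnitude-based classification.
#'
#' @param fit A `vc_fit` with `day_of_week` among its covariates.
#' @param conf_level Confidence level; default 0.95.
#' @param p_adjust `"none"` (default, mirroring the unadjusted
#'   presentation) or `"holm"`.
#' @return A list of class `dow_effects`: `adjusted_means` (tibble),
#'   `contrasts` (tibble), `highest_lowest` (one-row MBI-effect tibble).
#' @export
day_of_week_effects <- function(fit, conf_level = 0.95,
                                p_adjust = c("none", "holm")) {
  stopifnot(inherits(fit, "vc_fit"))
  p_adjust <- match.arg(p_adjust)
  if (!"day_of_week" %in% fit$covariates) {
    abort("day_of_week was not fitted as a covariate", class = "ebvar_validation_error")
  }
  days <- levels(fit$data$day_of_week)
  if (length(days) < 2) {
    abort("Fewer than two day-of-week levels present", class = "ebvar_estimation_error")
  }
  missing_days <- setdiff(.day_levels, days)
  if (length(missing_days) > 0) {
    warn(sprintf("Day level(s) absent from data, contrasts skipped: %s",
                 paste(missing_days, collapse = ", ")))
  }
  beta <- setNames(fit$fixed$estimate, fit$fixed$term)
  V <- fit$vcov_fixed
  terms <- fit$fixed$term
  tcrit <- qt(1 - (1 - conf_level) / 2, fit$df_resid)

  # design row for each day at covariate means / averaged factor levels
  x_for_day <- function(day) {
    x <- setNames(numeric(length(terms)), terms)
    x["(Intercept)"] <- 1
    for (col in names(fit$covariate_sd)) {
      if (col %in% terms) x[col] <- mean(fit$data[[col]], na.rm = TRUE)
    }
    if ("sexmale" %in% terms) x["sexmale"] <- mean(fit$data$sex == "male")
    dterm <- paste0("day_of_week", day)
    if (dterm %in% terms) x[dterm] <- 1
    x
  }
  means <- purrr::map_dfr(days, function(day) {
    x <- x_for_day(day)
    est <- sum(x * beta)
    se <- sqrt(drop(t(x) %*% V %*% x))
    tibble::tibble(
      day_of_week = day,
      mean_log = est, se_log = se,
      adjusted_mean = back_transform(est, fit$offset),
      ci_lo = back_transform(est - tcrit * se, fit$offset),
      ci_hi = back_transform(est + tcrit * se, fit$offset)
    )
  })

  # pairwise contrasts touch only the day dummies
  pairs <- utils::combn(days, 2, simplify = FALSE)
  contrasts <- purrr::map_dfr(pairs, function(p) {
    x <- setNames(numeric(length(terms)), terms)
    d1 <- paste0("day_of_week", p[1]); d2 <- paste0("day_of_week", p[2])
    if (d1 %in% terms) x[d1] <- 1
    if (d2 %in% terms) x[d2] <- -1
    est <- sum(x * beta)
    se <- sqrt(drop(t(x) %*% V %*% x))
    tibble::tibble(
      contrast = paste(p[1], "-", p[2]),
      effect_log = est, se_log = se,
      effect_pct = pct_from_log(est),
      ci_lo_pct = pct_from_log(est - tcrit * se),
      ci_hi_pct = pct_from_log(est + tcrit * se),
      p_value = 2 * pt(-abs(est / se), fit$df_resid)
    )
  })
  if (p_adjust == "holm") {
    contrasts$p_value <- stats::p.adjust(contrasts$p_value, method = "holm")
  }

  hi <- means$day_of_week[which.max(means$mean_log)]
  lo <- means$day_of_week[which.min(means$mean_log)]
  x <- setNames(numeric(length(terms)), terms)
  dhi <- paste0("day_of_week", hi); dlo <- paste0("day_of_week", lo)
  if (dhi %in% terms) x[dhi] <- 1
  if (dlo %in% terms) x[dlo] <- -1
  est <- sum(x * beta)
  se <- sqrt(drop(t(x) %*% V %*% x))
  swe <- smallest_worthwhile_effect(sqrt(pmax(fit$sigma2_between, 1e-12)))
  highest_lowest <- .mbi_effect_row(
    sprintf("%s: highest (%s) - lowest (%s) day", fit$outcome, hi, lo),
    est, se, fit$df_resid, swe, conf_level
  )

  structure(
    list(
      outcome = fit$outcome,
      adjusted_means = means,
      contrasts = contrasts,
      highest_lowest = highest_lowest
    ),
    class = "dow_effects"
  )
}

#' @exportS3Method base::print
print.dow_effects <- function(x, ...) {
  cat(sprintf("Day-of-week effects for %s\n", x$outcome))
  print(dplyr::select(x$adjusted_means, "day_of_week", "adjusted_mean",
                      "ci_lo", "ci_hi"))
  hl <- x$highest_lowest
  cat(sprintf(
    "Highest-lowest day: %.1f%% (%.1f, %.1f%%), %s %s\n",
    hl$effect_pct, hl$ci_lo_pct, hl$ci_hi_pct, hl$qualifier, hl$direction
  ))
  invisible(x)
}

#' Human-readable MBI phrasing
#'
#' @param effects An MBI-effect tibble (rows from [covariate_effect()],
#'   [order_effect()] or the `highest_lowest` element of
#'   [day_of_week_effects()]).
#' @return Character vector, one sentence per effect.
#' @export
describe_effects <- function(effects) {
  purrr::pmap_chr(effects, function(label, effect_pct, ci_lo_pct, ci_hi_pct,
                                    clarity, direction, qualifier, ...) {
    if (clarity == "unclear") {
      sprintf("%s: %.1f%% (%.1f, %.1f%%) - unclear", label, effect_pct,
              ci_lo_pct, ci_hi_pct)
    } else {
      sprintf("%s: %.1f%% (%.1f, %.1f%%) - %s %s", label, effect_pct,
              ci_lo_pct, ci_hi_pct, qualifier, direction)
    }
  })
}
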