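test_that("smallest worthwhile effect is 0.2 between-subject SD, linear", {
  expect_equal(smallest_worthwhile_effect(0.10), 0.02)
  expect_equal(smallest_worthwhile_effect(0.20), 2 * smallest_worthwhile_effect(0.10))
  expect_error(smallest_worthwhile_effect(0), class = "ebvar_domain_error")
})

test_that("substantiality probabilities follow the central t distribution", {
  # estimate exactly at the threshold: crossing probability is one half
  p <- substantiality_probabilities(0.02, 0.005, 25, 0.02)
  expect_equal(p$p_positive, 0.5)
  # b = 2 swe, se = swe/2, df = 30: p_positive = P(T_30 > -2)
  p <- substantiality_probabilities(0.04, 0.01, 30, 0.02)
  expect_equal(p$p_positive, pt(2, 30))
  expect_equal(p$p_positive, 0.9727, tolerance = 1e-4)
  # a near-degenerate se concentrates all mass in the trivial band
  p <- substantiality_probabilities(0, 1e-9, 30, 0.02)
  expect_equal(unlist(p), c(p_positive = 0, p_trivial = 1, p_negative = 0),
               tolerance = 1e-12)
  expect_error(substantiality_probabilities(0, 0, 30, 0.02),
               class = "ebvar_domain_error")
  expect_error(substantiality_probabilities(0, 1, 0.5, 0.02),
               class = "ebvar_domain_error")
})

test_that("classification applies the dual 5% rule and the probabilistic scale", {
  c1 <- classify_effect(0.20, 0.70, 0.10)
  expect_equal(c1$clarity, "unclear")
  c2 <- classify_effect(0.998, 0.002, 0)
  expect_equal(unlist(c2), c(clarity = "clear", direction = "increase",
                             qualifier = "most likely"))
  c3 <- classify_effect(0.60, 0.39, 0.01)
  expect_equal(c3$direction, "increase")
  expect_equal(c3$qualifier, "possible")
  # boundary probabilities fall in the higher bin
  expect_equal(classify_effect(0.75, 0.25, 0)$qualifier, "likely")
  expect_equal(classify_effect(0.95, 0.05, 0)$qualifier, "very likely")
  # direction ties break toward trivial
  expect_equal(classify_effect(0.5, 0.5, 0)$direction, "trivial")
})

test_that("probabilities sum to one and negation symmetry holds", {
  set.seed(42)
  n <- 1000
  b <- rnorm(n, 0, 0.1)
  se <- runif(n, 0.001, 0.2)
  df <- sample(2:200, n, replace = TRUE)
  swe <- runif(n, 0.001, 0.1)
  p <- substantiality_probabilities(b, se, df, swe)
  expect_true(all(abs(p$p_positive + p$p_trivial + p$p_negative - 1) < 1e-9))
  pneg <- substantiality_probabilities(-b, se, df, swe)
  expect_equal(p$p_positive, pneg$p_negative, tolerance = 1e-12)
  expect_equal(p$p_trivial, pneg$p_trivial, tolerance = 1e-9)
  cls <- classify_effect(p)
  clsneg <- classify_effect(pneg)
  expect_equal(cls$clarity, clsneg$clarity)
  swap <- c(increase = "decrease", decrease = "increase", trivial = "trivial")
  expect_equal(unname(swap[cls$direction]), clsneg$direction)
})

test_that("p_positive is monotone in the effect size", {
  b_grid <- seq(-0.2, 0.2, by = 0.01)
  p <- substantiality_probabilities(b_grid, 0.05, 30, 0.02)
  expect_true(all(diff(p$p_positive) > 0))
  expect_true(all(diff(p$p_negative) < 0))
})

test_that("with vanishing se the classification becomes the sign of |b| - swe", {
  se <- 1e-10
  expect_equal(classify_effect(
    substantiality_probabilities(0.05, se, 30, 0.02))$direction, "increase")
  expect_equal(classify_effect(
    substantiality_probabilities(-0.05, se, 30, 0.02))$direction, "decrease")
  expect_equal(classify_effect(
    substantiality_probabilities(0.01, se, 30, 0.02))$direction, "trivial")
})

test_that("covariate effects use 2 SD for numeric and level difference for sex", {
  cfg <- one_outcome_config(
    120, sigma_b = 0.2, sigma_w = 0.2,
    covariate_effects = tibble::tibble(
      outcome = "tee_kcal", sex_male = 0.3, injury_level = 0.02
    )
  )
  ch <- generate_cohort(cfg, seed = 8)
  fit <- fit_variance_model(ch$records, ch$subjects, "tee_kcal",
                            covariates = c("sex", "injury_level", "age"))
  sexe <- covariate_effect(fit, "sex")
  beta <- fit$fixed$estimate[fit$fixed$term == "sexmale"]
  expect_equal(sexe$effect_log, beta)
  expect_equal(sexe$effect_pct, pct_from_log(beta))

  inje <- covariate_effect(fit, "injury_level")
  b_inj <- fit$fixed$estimate[fit$fixed$term == "injury_level_code"]
  sd_inj <- sd(fit$data$injury_level_code)
  expect_equal(inje$effect_log, 2 * sd_inj * b_inj)

  # unit invariance: the 2-SD age effect does not depend on the age unit
  subj_months <- ch$subjects
  subj_months$age <- subj_months$age * 12
  fit2 <- fit_variance_model(ch$records, subj_months, "tee_kcal",
                             covariates = c("sex", "injury_level", "age"))
  expect_equal(covariate_effect(fit, "age")$effect_log,
               covariate_effect(fit2, "age")$effect_log, tolerance = 1e-6)

  expect_error(covariate_effect(fit, "wear_time"),
               class = "ebvar_validation_error")
})

test_that("order effect scales the daily drift to the whole week", {
  cfg <- one_outcome_config(60, sigma_b = 0.2, sigma_w = 0.2,
                            outcome = "intake_kcal", order_drift_pct = -15)
  ch <- generate_cohort(cfg, seed = 9)
  fit <- fit_variance_model(ch$records, ch$subjects, "intake_kcal",
                            covariates = c("sex", "order_index"))
  eff <- order_effect(fit, n_days = 7)
  beta <- fit$fixed$estimate[fit$fixed$term == "order_index"]
  expect_equal(eff$effect_log, 6 * beta)
  # a drift of exactly log(0.85)/6 per day back-transforms to -15% per week
  expect_equal(pct_from_log(6 * log(0.85) / 6), -15, tolerance = 1e-12)
  expect_error(order_effect(fit_variance_model(
    ch$records, ch$subjects, "intake_kcal", covariates = "sex"
  )), class = "ebvar_validation_error")
})

test_that("day-of-week machinery recovers injected weekday structure", {
  dow <- c(-0.1, 0, 0, 0, 0.4, 0.4, 0) # Friday/Saturday bump
  cfg <- one_outcome_config(250, sigma_b = 0.2, sigma_w = 0.2,
                            outcome = "alcohol_pct",
                            dow_effects = list(alcohol_pct = dow))
  ch <- generate_cohort(cfg, seed = 10)
  fit <- fit_variance_model(ch$records, ch$subjects, "alcohol_pct",
                            covariates = c("sex", "day_of_week"), offset = 1)
  d <- day_of_week_effects(fit)
  means <- d$adjusted_means
  expect_equal(nrow(means), 7)
  expect_equal(nrow(d$contrasts), choose(7, 2))
  fri_mon <- d$contrasts[d$contrasts$contrast == "Mon - Fri", ]
  expect_lt(fri_mon$effect_log, 0)
  expect_lt(fri_mon$p_value, 0.001)
  # highest/lowest fitted days match the injected pattern
  hi <- means$day_of_week[which.max(means$mean_log)]
  expect_true(hi %in% c("Fri", "Sat"))
  expect_equal(means$day_of_week[which.min(means$mean_log)], "Mon")
  # internal consistency: highest-lowest percent equals the max-min contrast
  expect_equal(
    d$highest_lowest$effect_log,
    max(means$mean_log) - min(means$mean_log),
    tolerance = 1e-12
  )
  expect_equal(d$highest_lowest$clarity, "clear")
  expect_equal(d$highest_lowest$direction, "increase")
  # Holm adjustment only increases p-values
  dh <- day_of_week_effects(fit, p_adjust = "holm")
  expect_true(all(dh$contrasts$p_value >= d$contrasts$p_value - 1e-12))
  expect_s3_class(autoplot(d), "ggplot")
})

test_that("adjusted means agree with emmeans on the same model", {
  skip_if_not_installed("emmeans")
  cfg <- one_outcome_config(40, sigma_b = 0.2, sigma_w = 0.2)
  ch <- generate_cohort(cfg, seed = 12)
  fit <- fit_variance_model(ch$records, ch$subjects, "tee_kcal",
                            covariates = c("age", "sex", "day_of_week"))
  em <- suppressMessages(as.data.frame(emmeans::emmeans(
    fit$model, "day_of_week", lmer.df = "asymptotic",
    weights = "proportional"
  )))
  ours <- day_of_week_effects(fit)$adjusted_means
  expect_equal(ours$mean_log, em$emmean[match(ours$day_of_week, em$day_of_week)],
               tolerance = 1e-6)
})

test_that("zero-effect data classify as trivial across contrast types", {
  cfg <- one_outcome_config(300, sigma_b = 0.3, sigma_w = 0.1)
  ch <- generate_cohort(cfg, seed = 13)
  fit <- fit_variance_model(ch$records, ch$subjects, "tee_kcal")
  eff <- dplyr::bind_rows(
    covariate_effect(fit, "age"),
    order_effect(fit)
  )
  # null configured effects: estimates stay within estimation noise of zero
  expect_true(all(abs(eff$effect_log) < 4 * eff$se_log + 1e-6))
  expect_true(all(abs(eff$effect_pct) < 10))
  expect_true(all(eff$p_positive + eff$p_trivial + eff$p_negative - 1 < 1e-9))
  desc <- describe_effects(eff)
  expect_length(desc, 2)
  expect_match(desc[1], "%")
})
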