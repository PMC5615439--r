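test_that("REML components match the one-way ANOVA oracle on balanced data", {
  recs <- make_balanced_records(n_subjects = 5, n_days = 4,
                                sigma_b = 0.2, sigma_w = 0.1, seed = 101)
  subj <- make_subjects(5)
  fit <- fit_variance_model(recs, subj, "tee_kcal", covariates = character(0))
  oracle <- anova_components(log(recs$tee_kcal), recs$subject_id)
  expect_equal(fit$sigma2_within, oracle$sigma2_within, tolerance = 1e-6)
  expect_equal(fit$sigma2_between, oracle$sigma2_between, tolerance = 1e-6)
  expect_equal(
    icc_from_components(fit),
    oracle$sigma2_between / (oracle$sigma2_between + oracle$sigma2_within),
    tolerance = 1e-6
  )
})

test_that("no between-subject signal gives a near-zero between variance", {
  set.seed(5)
  recs <- make_balanced_records(n_subjects = 8, n_days = 6,
                                sigma_b = 0, sigma_w = 0.1, seed = 55)
  subj <- make_subjects(8)
  fit <- fit_variance_model(recs, subj, "tee_kcal", covariates = character(0))
  expect_lt(fit$sigma2_between, 0.005)
  expect_gt(fit$sigma2_within, 0)
})

test_that("variance model handles unbalanced day counts and reports sizes", {
  recs <- make_balanced_records(n_subjects = 6, n_days = 5, seed = 77)
  recs <- recs[-c(2, 9, 10, 23), ] # drop days unevenly
  subj <- make_subjects(6)
  fit <- fit_variance_model(
    recs, subj, "tee_kcal",
    covariates = c("age", "injury_level", "sex", "day_of_week", "order_index")
  )
  expect_s3_class(fit, "vc_fit")
  expect_equal(fit$n_obs, nrow(recs))
  expect_equal(fit$n_subjects, 6)
  expect_equal(fit$df_resid, fit$n_obs - nrow(fit$fixed) - 6)
  # constant covariate is a singular design, reported by name
  subj_const <- subj
  subj_const$age <- 40
  expect_error(
    fit_variance_model(recs, subj_const, "tee_kcal", covariates = "age"),
    "age", class = "ebvar_estimation_error"
  )
  expect_error(
    fit_variance_model(recs[1:2, ], subj, "tee_kcal", covariates = character(0)),
    class = "ebvar_estimation_error"
  )
})

test_that("tidy and glance expose coefficients and variance components", {
  recs <- make_balanced_records(n_subjects = 5, n_days = 4, seed = 31)
  subj <- make_subjects(5)
  fit <- fit_variance_model(recs, subj, "tee_kcal", covariates = c("age", "sex"))
  td <- tidy(fit)
  expect_true(all(c("sexmale", "age", "(Intercept)") %in% td$term))
  expect_equal(sum(td$effect == "ran_pars"), 2)
  expect_equal(tidy(fit, "fixed")$term, fit$fixed$term)
  gl <- glance(fit)
  expect_equal(gl$icc, icc_from_components(fit))
  expect_equal(gl$n_obs, 20)
})

test_that("ICC is the between share of total variance, truncated at zero", {
  expect_equal(icc_from_components(0.5, 0.5), 0.5)
  expect_equal(icc_from_components(0.2, 0.6), 0.25)
  expect_equal(icc_from_components(1, 0), 1)
  expect_equal(icc_from_components(-0.1, 0.4), 0) # negative ANOVA estimate
  expect_error(icc_from_components(0, 0), class = "ebvar_domain_error")
})

test_that("prophecy formula gives exact days and satisfies the step-up identity", {
  dn <- days_needed(c(0.80, 0.50, 0.20), icc_target = 0.80)
  expect_equal(dn$days_needed_real, c(1, 4, 16), tolerance = 1e-9)
  expect_equal(dn$days_needed, c(1L, 4L, 16L))
  # plugging N back into the step-up formula recovers the target exactly
  expect_equal(
    spearman_brown_step_up(dn$icc_single, dn$days_needed_real),
    rep(0.80, 3), tolerance = 1e-12
  )
  # monotone decreasing in single-day ICC
  grid <- days_needed(seq(0.05, 0.95, by = 0.05))
  expect_true(all(diff(grid$days_needed_real) < 0))
  expect_true(all(
    abs(spearman_brown_step_up(grid$icc_single, grid$days_needed_real) - 0.8)
    < 1e-12
  ))
  expect_error(days_needed(0), class = "ebvar_domain_error")
  expect_error(days_needed(1), class = "ebvar_domain_error")
  expect_error(days_needed(0.5, icc_target = 1), class = "ebvar_domain_error")
})

test_that("intra-individual CV matches hand arithmetic and is scale invariant", {
  rec3 <- tibble::tibble(
    subject_id = "S01", order_index = 1:3,
    day_of_week = c("Mon", "Tue", "Wed"), wear_minutes = 1440,
    tee_kcal = c(1, 2, 3)
  )
  cv <- intra_individual_cv(rec3, "tee_kcal")
  expect_equal(cv$cv_pct, 50) # mean 2, sample SD 1

  same <- rec3
  same$tee_kcal <- 5
  expect_equal(intra_individual_cv(same, "tee_kcal")$cv_pct, 0)

  scaled <- rec3
  scaled$tee_kcal <- rec3$tee_kcal * 37.5
  expect_equal(intra_individual_cv(scaled, "tee_kcal")$cv_pct, 50)

  zero <- rec3
  zero$tee_kcal <- 0
  expect_warning(expect_error(intra_individual_cv(zero, "tee_kcal")))
})

test_that("cohort CV summary uses a t interval across subjects", {
  recs <- make_balanced_records(n_subjects = 10, n_days = 5,
                                sigma_b = 0.1, sigma_w = 0.2, seed = 91)
  cv <- intra_individual_cv(recs, "tee_kcal")
  s <- summarise_cv(cv)
  expect_equal(s$n_subjects, 10)
  expect_equal(s$cv_mean_pct, mean(cv$cv_pct))
  half <- qt(0.975, 9) * sd(cv$cv_pct) / sqrt(10)
  expect_equal(c(s$cv_lo95, s$cv_hi95),
               mean(cv$cv_pct) + c(-half, half))
})

test_that("reliability table is deterministic and flags degenerate outcomes", {
  recs <- make_balanced_records(n_subjects = 8, n_days = 6,
                                sigma_b = 0.25, sigma_w = 0.25, seed = 13)
  recs$copy_kcal <- recs$tee_kcal
  # an outcome with no between-subject signal at all
  set.seed(14)
  recs$flat <- exp(rnorm(nrow(recs), 5, 0.1))
  subj <- make_subjects(8)
  tab <- reliability_table(
    recs, subj, outcomes = c("tee_kcal", "copy_kcal", "flat"),
    covariates = c("age", "sex"), apply_wear_filter = FALSE,
    offsets = c(tee_kcal = 0, copy_kcal = 0, flat = 0)
  )
  # identical data gives identical rows
  expect_equal(
    unlist(tab[tab$outcome == "tee_kcal", -1]),
    unlist(tab[tab$outcome == "copy_kcal", -1])
  )
  flat_row <- tab[tab$outcome == "flat", ]
  if (flat_row$unreliable) {
    expect_true(is.na(flat_row$days_needed))
  } else {
    # near-zero ICC needs far more days than observed
    expect_true(flat_row$beyond_observed)
  }
  expect_s3_class(autoplot(tab), "ggplot")
  expect_named(reliability_fits(tab), c("tee_kcal", "copy_kcal", "flat"))
})
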