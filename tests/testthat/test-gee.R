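test_that("exchangeable GEE matches explicit GLS on a 2x2 toy table", {
  sm <- toy_summaries(rep(c("A", "B", "C", "D"), each = 2),
                      rep(1:2, 4), c(70, 74, 80, 78, 75, 71, 69, 73))
  pr <- toy_profiles(c("A", "B", "C", "D"),
                     c("digoxin", "beta_blocker", "digoxin", "beta_blocker"))
  fit <- fit_gee_exchangeable(sm, pr)
  X <- cbind(1, rep(c(1, 0, 1, 0), each = 2))
  V1 <- fit$phi * matrix(c(1, fit$rho_hat, fit$rho_hat, 1), 2)
  V <- matrix(0, 8, 8)
  for (i in 0:3) V[2 * i + 1:2, 2 * i + 1:2] <- V1
  oracle <- gls_brute(sm$mean_hr_bpm, X, V)
  expect_lt(max(abs(unname(fit$beta) - as.numeric(oracle))), 1e-8)
  expect_true(fit$converged)
})

test_that("GEE with the correlation fixed at zero is exactly OLS", {
  set.seed(4)
  sm <- toy_summaries(rep(sprintf("P%02d", 1:8), each = 3), rep(1:3, 8),
                      75 + rnorm(24, sd = 4))
  pr <- toy_profiles(sprintf("P%02d", 1:8),
                     rep(c("digoxin", "beta_blocker"), 4))
  fit <- fit_gee_exchangeable(sm, pr, rho_fix = 0)
  dat <- merge(sm, pr, by = "patient_id")
  ols <- coef(lm(mean_hr_bpm ~ I(arm == "digoxin"), data = dat))
  expect_lt(max(abs(unname(fit$beta) - unname(ols))), 1e-10)
})

test_that("GEE with one observation per patient equals OLS", {
  set.seed(5)
  sm <- toy_summaries(sprintf("P%02d", 1:12), rep(1, 12), 75 + rnorm(12, sd = 5))
  pr <- toy_profiles(sprintf("P%02d", 1:12),
                     rep(c("digoxin", "beta_blocker"), 6))
  fit <- fit_gee_exchangeable(sm, pr)
  dat <- merge(sm, pr, by = "patient_id")
  ols <- coef(lm(mean_hr_bpm ~ I(arm == "digoxin"), data = dat))
  expect_lt(max(abs(unname(fit$beta) - unname(ols))), 1e-10)
})

test_that("the arm estimate is invariant to week relabeling", {
  wk <- simulate_weekly_cohort(cohort_config(n_patients = 16, n_weeks = 5,
                                             seed = 6))
  fit <- fit_gee_exchangeable(wk$summaries, wk$profiles)
  shuffled <- wk$summaries
  set.seed(7)
  shuffled$week_index <- ave(shuffled$week_index, shuffled$patient_id,
                             FUN = sample)
  fit2 <- fit_gee_exchangeable(shuffled, wk$profiles)
  expect_equal(fit$beta, fit2$beta, tolerance = 1e-10)
})

test_that("sandwich standard errors are nonnegative and CIs bracket beta", {
  wk <- simulate_weekly_cohort(cohort_config(n_patients = 30, n_weeks = 8,
                                             seed = 8))
  fit <- fit_gee_exchangeable(wk$summaries, wk$profiles,
                              model_spec(c("age", "gender", "heart_failure",
                                           "nt_probnp")))
  expect_true(all(fit$robust_se >= 0))
  expect_true(all(fit$ci95[, "lower"] <= fit$beta &
                    fit$beta <= fit$ci95[, "upper"]))
  expect_gt(fit$rho_hat, -1 / 7)
  expect_lt(fit$rho_hat, 1)
})

test_that("singular designs fail with the collinear columns named", {
  wk <- simulate_weekly_cohort(cohort_config(n_patients = 10, n_weeks = 3,
                                             seed = 9))
  wk$profiles$heart_failure <- FALSE  # constant -> collinear with intercept
  expect_error(
    fit_gee_exchangeable(wk$summaries, wk$profiles,
                         model_spec(c("heart_failure"))),
    "heart_failure")
})

test_that("injected arm effects are recovered without bias", {
  est <- vapply(1:40, function(r) {
    wk <- simulate_weekly_cohort(cohort_config(n_patients = 60, n_weeks = 10,
                                               treatment_effect_bpm = 2,
                                               seed = 100 + r))
    fit_gee_exchangeable(wk$summaries, wk$profiles)$beta["arm_digoxin"]
  }, 0)
  expect_lt(abs(mean(est) - 2), 3 * sd(est) / sqrt(length(est)) + 0.05)
})

test_that("the analysis suite returns the five fit families with counts", {
  wk <- simulate_weekly_cohort(cohort_config(n_patients = 30, n_weeks = 10,
                                             seed = 10))
  suite <- run_analysis_suite(wk$summaries, wk$profiles)
  expect_named(suite, c("unadjusted", "adjusted", "activity_adjusted",
                        "subgroup_low", "subgroup_minimum_recommended",
                        "subgroup_recommended"))
  ok <- !vapply(suite, inherits, TRUE, "gee_skip")
  expect_true(all(ok[c("unadjusted", "adjusted", "activity_adjusted")]))
  for (nm in names(suite)[ok]) {
    expect_s3_class(suite[[nm]], "gee_fit")
    expect_true(suite[[nm]]$n_weeks_total >= suite[[nm]]$n_patients)
  }
  # fitted subgroups report exactly the week counts of their activity band
  bands <- table(wk$summaries$activity_category)
  for (band in names(bands)) {
    f <- suite[[paste0("subgroup_", band)]]
    if (inherits(f, "gee_fit")) {
      expect_equal(f$n_weeks_total, unname(bands[band]))
    } else {
      expect_match(f$reason, "2 patients")
    }
  }
})

test_that("subgroup filtering keeps week-level records by activity band", {
  sm <- toy_summaries(rep(c("A", "B", "C", "D"), each = 3), rep(1:3, 4),
                      75 + rnorm(12), steps = rep(c(10000, 20000, 35000), 4))
  pr <- toy_profiles(c("A", "B", "C", "D"),
                     c("digoxin", "beta_blocker", "digoxin", "beta_blocker"))
  d <- afwear:::build_design(sm, pr, model_spec(subgroup = "low"))
  expect_equal(length(d$y), 4L)  # one low week per patient
  d2 <- afwear:::build_design(sm, pr, model_spec(subgroup = "recommended"))
  expect_equal(length(d2$y), 4L)
})

test_that("group difference test matches rank formulas and conventions", {
  kw <- group_difference_test(c(1, 2, 3), c(4, 5, 6), normal = FALSE)
  expect_equal(kw$statistic, kw_brute(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-10)
  expect_equal(kw$statistic, 3.857, tolerance = 1e-3)
  same <- group_difference_test(c(1, 2, 3), c(1, 2, 3), normal = FALSE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(group_difference_test(c(1, 1), c(1, 1), normal = TRUE),
               "zero variance")
  expect_error(group_difference_test(1, c(1, 2), normal = TRUE), "n >= 2")
})

test_that("the t-test branch holds its nominal type-I error", {
  set.seed(11)
  rej <- mean(vapply(1:1000, function(i) {
    group_difference_test(rnorm(15), rnorm(15), normal = TRUE)$p_value < 0.05
  }, TRUE))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("repeated-measures sample size reduces to the classical formula", {
  # rho = 0, m = 1: n = 2 (z_a + z_b)^2 sigma^2 / delta^2
  out <- power_repeated_measures(2, 6, 0, 1)
  z <- qnorm(0.975) + qnorm(0.9)
  expect_equal(out$n_per_arm, ceiling(2 * z^2 * 36 / 4))
  # doubling delta shrinks n about fourfold
  n1 <- power_repeated_measures(1, 6, 0.5, 10)$n_per_arm
  n2 <- power_repeated_measures(2, 6, 0.5, 10)$n_per_arm
  expect_lt(abs(n1 / n2 - 4), 0.2)
  expect_error(power_repeated_measures(0, 6, 0.5, 10), "nonzero")
})

test_that("analytic power agrees with simulation at the computed n", {
  out <- power_repeated_measures(2, 6, 0.91, 20, alpha = 0.05, power = 0.9)
  sim <- power_simulate_repeated(out$n_per_arm, 2, 6, 0.91, 20,
                                 n_sim = 3000, seed = 12)
  expect_lt(abs(sim - 0.9), 0.03)
})
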