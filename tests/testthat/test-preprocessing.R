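test_that("minute pooling averages heart rate and sums steps", {
  s <- toy_stream(hr_offsets_s = c(5, 20, 40), hr_values = c(70, 72, 74),
                  step_offsets_s = c(0, 10, 30), step_values = c(5, 0, 7))
  ms <- pool_to_minutes(s)
  expect_equal(length(ms$hr_bpm), 1L)
  expect_equal(ms$hr_bpm, 72)
  expect_equal(ms$steps, 12)
  expect_equal(ms$mask, 0L)
})

test_that("empty minutes are missing with mask 1; empty streams error", {
  # records in minutes 1 and 3, nothing in minute 2
  s <- toy_stream(hr_offsets_s = c(0, 125), hr_values = c(70, 80),
                  step_offsets_s = c(0, 125), step_values = c(1, 2))
  ms <- pool_to_minutes(s)
  expect_equal(length(ms$hr_bpm), 3L)
  expect_true(is.na(ms$hr_bpm[2]) && is.na(ms$steps[2]))
  expect_equal(ms$mask, c(0L, 1L, 0L))
  expect_error(pool_to_minutes(s[0, ]), "empty")
  s$value[1] <- NaN
  expect_error(pool_to_minutes(s), "non-finite")
})

test_that("pooling a one-sample-per-minute stream reproduces the samples", {
  n <- 30
  vals <- 60 + seq_len(n)
  s <- toy_stream(hr_offsets_s = (seq_len(n) - 1) * 60, hr_values = vals,
                  step_offsets_s = (seq_len(n) - 1) * 60,
                  step_values = seq_len(n))
  ms <- pool_to_minutes(s)
  expect_equal(ms$hr_bpm, vals)
  expect_equal(ms$steps, as.numeric(seq_len(n)))
})

test_that("per-patient normalization gives zero-mean unit-sd HR and [0,1] steps", {
  co <- generate_cohort(cohort_config(n_patients = 2, n_weeks = 1, seed = 13))
  ms <- pool_to_minutes(co$streams[[1]])
  nm <- normalize_patient(ms)
  obs <- !nm$hr_missing
  expect_lt(abs(mean(nm$hr_bpm[obs])), 1e-9)
  expect_lt(abs(sd(nm$hr_bpm[obs]) - 1), 1e-9)
  expect_true(all(nm$steps >= 0 & nm$steps <= 1))
  # masked minutes carry the neutral fill value 0
  expect_true(all(nm$hr_bpm[nm$hr_missing] == 0))
  expect_true(all(nm$steps[nm$steps_missing] == 0))
})

test_that("normalization hand example and degenerate guards", {
  s <- toy_stream(hr_offsets_s = c(0, 60, 120), hr_values = c(60, 70, 80),
                  step_offsets_s = c(0, 60, 120), step_values = c(0, 50, 100))
  nm <- normalize_patient(pool_to_minutes(s))
  expect_equal(nm$steps, c(0, 0.5, 1.0))
  # all-zero step channel stays zero (guarded denominator)
  s0 <- toy_stream(hr_offsets_s = c(0, 60, 120), hr_values = c(60, 70, 80),
                   step_offsets_s = c(0, 60, 120), step_values = c(0, 0, 0))
  expect_equal(normalize_patient(pool_to_minutes(s0))$steps, c(0, 0, 0))
  sc <- toy_stream(hr_offsets_s = c(0, 60), hr_values = c(70, 70),
                   step_offsets_s = c(0, 60), step_values = c(1, 1))
  expect_error(normalize_patient(pool_to_minutes(sc)), "zero variance")
})

test_that("window extraction counts and availability follow the stagger rule", {
  mk <- function(T_min) {
    s <- toy_stream(hr_offsets_s = (seq_len(T_min) - 1) * 60,
                    hr_values = 70 + sin(seq_len(T_min)),
                    step_offsets_s = (seq_len(T_min) - 1) * 60,
                    step_values = rep(c(0, 5), length.out = T_min))
    normalize_patient(pool_to_minutes(s))
  }
  expect_equal(nrow(extract_windows(mk(480))$index), 5L)   # floor((480-240)/60)+1
  expect_equal(nrow(extract_windows(mk(240))$index), 1L)   # boundary
  expect_equal(nrow(extract_windows(mk(239))$index), 0L)   # shorter than window
  ws <- extract_windows(mk(480))
  expect_true(all(ws$index$available))
  expect_equal(dim(ws$values), c(5L, 240L, 3L))
})

test_that("window extraction is translation-consistent under a stride shift", {
  T_min <- 600
  vals <- 70 + cumsum(rnorm(T_min))
  mk <- function(from) {
    s <- toy_stream(hr_offsets_s = (seq(from, T_min) - 1) * 60,
                    hr_values = vals[seq(from, T_min)],
                    step_offsets_s = (seq(from, T_min) - 1) * 60,
                    step_values = rep(1, T_min - from + 1))
    extract_windows(normalize_patient(pool_to_minutes(s)))
  }
  full <- mk(1)
  shifted <- mk(61)  # drop exactly one stride from the front
  expect_equal(nrow(shifted$index), nrow(full$index) - 1L)
  expect_equal(shifted$index$window_start,
               full$index$window_start[-1])
})

test_that("fully missing windows are flagged unavailable", {
  # 240 present minutes, then a 240-minute hole, then 240 more
  off <- c(0:239, 480:719) * 60
  s <- toy_stream(hr_offsets_s = off, hr_values = 70 + rnorm(480),
                  step_offsets_s = off, step_values = rep(1, 480))
  ws <- extract_windows(normalize_patient(pool_to_minutes(s)),
                        stride_min = 240)
  expect_equal(ws$index$available, c(TRUE, FALSE, TRUE))
})

test_that("weekly summaries apply the CDC thresholds and conserve steps", {
  wk_min <- 10080
  steps <- rep(0, 3 * wk_min)
  steps[seq(1, wk_min, 2)] <- 14999 / length(seq(1, wk_min, 2)) # ~low
  s <- toy_stream(hr_offsets_s = (seq_len(3 * wk_min) - 1) * 60,
                  hr_values = rep(70, 3 * wk_min),
                  step_offsets_s = (seq_len(3 * wk_min) - 1) * 60,
                  step_values = c(rep(14999 / wk_min, wk_min),
                                  rep(15000 / wk_min, wk_min),
                                  rep(30000 / wk_min, wk_min)))
  ms <- pool_to_minutes(s)
  wk <- weekly_summaries(ms)
  expect_equal(as.character(wk$activity_category),
               c("low", "minimum_recommended", "recommended"))
  expect_equal(wk$total_steps, c(14999, 15000, 30000), tolerance = 1e-8)
  expect_equal(wk$mean_hr_bpm, rep(70, 3))
})

test_that("weekly summaries truncate at max_weeks and drop sparse weeks", {
  co <- generate_cohort(cohort_config(n_patients = 2, n_weeks = 3,
                                      missing_frac = 0, seed = 17))
  ms <- pool_to_minutes(co$streams[[1]])
  expect_lte(nrow(weekly_summaries(ms, max_weeks = 2)), 2L)
  # blank out week 2 completely: it must be excluded
  rng <- 10081:20160
  ms$hr_bpm[rng] <- NA
  ms$hr_missing[rng] <- TRUE
  wk <- weekly_summaries(ms)
  expect_false(2L %in% wk$week_index)
})

test_that("daytime correlation matches the explicit rank formula and bands", {
  # strictly monotone pair: rho = 1
  s <- toy_stream(hr_offsets_s = (0:9) * 60 + 8 * 3600, hr_values = 70 + (0:9),
                  step_offsets_s = (0:9) * 60 + 8 * 3600, step_values = 0:9)
  expect_equal(daytime_correlation(s)$rho, 1.0)
  # explicit 5-pair example: 1 - 6*4/120 = 0.8
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  s2 <- toy_stream(hr_offsets_s = (0:4) * 60 + 8 * 3600, hr_values = x,
                   step_offsets_s = (0:4) * 60 + 8 * 3600, step_values = y)
  expect_equal(daytime_correlation(s2)$rho, 0.8)
  expect_equal(daytime_correlation(s2)$rho, spearman_brute(x, y))
  # bands
  expect_error(daytime_correlation(s2[1:2, ]), "3 paired")
})

test_that("correlation bands follow the reporting convention", {
  pair_stream <- function(x, y) {
    toy_stream(hr_offsets_s = (seq_along(x) - 1) * 60 + 8 * 3600,
               hr_values = x,
               step_offsets_s = (seq_along(x) - 1) * 60 + 8 * 3600,
               step_values = y)
  }
  x <- 1:5
  weak <- daytime_correlation(pair_stream(x, c(4, 1, 2, 3, 5)))  # rho 0.4
  expect_equal(weak$rho, 0.4)
  expect_equal(weak$band, "weak to moderate")
  none <- daytime_correlation(pair_stream(x, c(2, 5, 3, 1, 4)))  # rho 0
  expect_equal(none$rho, 0)
  expect_equal(none$band, "very weak")
  strong <- daytime_correlation(pair_stream(x, c(2, 1, 4, 3, 5))) # rho 0.8
  expect_equal(strong$band, "strong")
  # nighttime-only records leave no daytime pairs
  s <- toy_stream(hr_offsets_s = (0:9) * 60, hr_values = 70 + (0:9) %% 3,
                  step_offsets_s = (0:9) * 60, step_values = (0:9) %% 4)
  expect_error(daytime_correlation(s), "3 paired")
})
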