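#' @title Synthetic two-arm wearables cohort
#' @description
#' `generate_cohort()` draws a complete synthetic cohort under a
#' [cohort_config()]: patient covariate profiles (arm, demographics,
#' biomarkers, 6-minute-walk measures, NYHA class) and per-patient raw sensor
#' streams (heart rate every `hr_interval_s` seconds, step counts per
#' minute), with device-off missingness applied and end-of-trial NYHA labels
#' linked to observed activity. All randomness derives from `config$seed`, so
#' repeated calls are byte-identical.
#'
#' Streams are long-format data frames with columns `patient_id`,
#' `timestamp` (POSIXct, UTC), `channel` (`"hr"` or `"steps"`) and `value`;
#' every emitted minute carries a step record (zeros included), so a missing
#' minute means the device was off or unreachable for both channels.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `profiles` (data frame, one row per patient)
#'   and `streams` (named list of per-patient long-format data frames).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 3, n_weeks = 1,
#'                                         seed = 42))
#' names(cohort$streams)
#' table(cohort$profiles$arm)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  profiles <- draw_profiles(config)
  streams <- vector("list", config$n_patients)
  names(streams) <- profiles$patient_id
  for (i in seq_len(config$n_patients)) {
    raw <- generate_patient_stream(config, profiles[i, ], patient_index = i)
    if (config$missing_frac > 0) {
      raw <- apply_missingness(raw, config$missing_frac, config$mean_gap_min,
                               seed = derive_seed(config$seed, 1000L + i))
    }
    streams[[i]] <- raw
  }
  profiles <- assign_nyha_labels(profiles, streams, config)
  list(profiles = profiles, streams = streams)
}

cohort_epoch <- function() as.POSIXct("2019-01-07 00:00:00", tz = "UTC")

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Classify a weekly step total into CDC activity bands
#'
#' Below 15,000 steps per week is `"low"`; 15,000 up to (but excluding)
#' 30,000 is `"minimum_recommended"` (the 150 min/week aerobic-activity
#' equivalent); 30,000 or more is `"recommended"` (300 min/week equivalent).
#'
#' @param total_steps Numeric vector of weekly step totals.
#' @return Factor with levels `low`, `minimum_recommended`, `recommended`.
#' @examples
#' activity_category(c(14999, 15000, 30000))
#' @export
activity_category <- function(total_steps) {
  cut(total_steps, breaks = c(-Inf, 15000, 30000, Inf), right = FALSE,
      labels = c("low", "minimum_recommended", "recommended"))
}

# Patient covariates. The latent activity multiplier `activity_level`
# (lognormal, median 1) scales each patient's step output and leaks, noisily,
# into 6MW distance and baseline NYHA so that functional measures carry real
# signal about capacity, as they do clinically.
draw_profiles <- function(config) {
  n <- config$n_patients
  set.seed(derive_seed(config$seed, 1L))
  arm <- sample(rep(c("digoxin", "beta_blocker"), length.out = n))
  activity_level <- exp(stats::rnorm(n, 0, 0.5))
  log_a <- log(activity_level)
  age <- clamp(stats::rnorm(n, 75.6, 8.4), 60, 92)
  gender <- ifelse(stats::runif(n) < 0.4, "woman", "man")
  heart_failure <- stats::runif(n) < 0.45
  nt_probnp <- exp(stats::rnorm(n, log(1099), 0.6))
  bmi <- clamp(stats::rnorm(n, 29, 5), 18, 45)
  ecg_hr <- clamp(stats::rnorm(n, 97.7, 20.4), 40, 180)
  # 6MW distance tracks functional capacity closely (it is the clinical
  # capacity measure), with moderate measurement noise
  smw_distance <- clamp(380 + 144 * log_a + stats::rnorm(n, 0, 50), 50, 650)
  full_time <- stats::runif(n) >= 0.15
  smw_time <- ifelse(full_time, 360, stats::runif(n, 200, 350))
  # baseline NYHA II/III/IV with marginal probabilities .72/.26/.02,
  # stochastically worse for low-capacity patients
  lat <- -0.8 * scale(log_a)[, 1] + stats::rnorm(n)
  cuts <- stats::qnorm(c(0.72, 0.98)) * sqrt(1 + 0.8^2)
  nyha_baseline <- c("II", "III", "IV")[findInterval(lat, cuts) + 1L]
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    arm = arm,
    age_years = age,
    gender = gender,
    heart_failure = heart_failure,
    nt_probnp_pg_ml = nt_probnp,
    bmi_kg_m2 = bmi,
    ecg_hr_bpm = ecg_hr,
    smw_distance_m = smw_distance,
    smw_time_s = smw_time,
    smw_speed_m_s = smw_distance / smw_time,
    nyha_baseline = factor(nyha_baseline, levels = c("II", "III", "IV")),
    nyha_final = factor(NA_character_, levels = c("I", "II", "III", "IV")),
    activity_level = activity_level,
    stringsAsFactors = FALSE
  )
}

# Per-minute step counts: zero-inflated Poisson bouts, gated to near-zero at
# night (23:00-07:00) unless night_gate is off. A patient's capacity scales
# the *frequency* of bouts, not their intensity: low-capacity patients walk
# less often at a similar cadence, so activity differences survive the
# per-patient [0,1] step normalization downstream. Expected weekly totals
# are ~26,880 * activity_level (night-gated).
draw_minute_steps <- function(config, activity_level, hour_of_day) {
  n_min <- length(hour_of_day)
  day <- hour_of_day >= 7 & hour_of_day < 23
  p_day <- min(0.10 * activity_level, 0.5)
  p_active <- if (config$night_gate) ifelse(day, p_day, 0.005)
              else rep(p_day, n_min)
  active <- stats::runif(n_min) < p_active
  steps <- integer(n_min)
  steps[active] <- stats::rpois(sum(active), 40)
  steps
}

generate_patient_stream <- function(config, profile, patient_index) {
  set.seed(derive_seed(config$seed, 100L + patient_index))
  n_min <- config$n_weeks * 7L * 24L * 60L
  minute <- seq_len(n_min) - 1L
  hour_of_day <- (minute %/% 60L) %% 24L + (minute %% 60L) / 60
  week <- minute %/% (7L * 24L * 60L)

  vc <- weekly_variance_components(config)
  mu <- config$baseline_hr_bpm +
    config$treatment_effect_bpm * (profile$arm == "digoxin") +
    stats::rnorm(1, 0, vc$intercept_sd)
  week_effect <- stats::rnorm(config$n_weeks, 0, vc$week_sd)[week + 1L]

  steps <- draw_minute_steps(config, profile$activity_level, hour_of_day)
  circadian <- config$circadian_amplitude_bpm *
    cos(2 * pi * (hour_of_day - 16) / 24)
  innov_sd <- config$within_patient_sd_bpm * sqrt(1 - config$ar_phi^2)
  noise <- as.numeric(stats::filter(stats::rnorm(n_min, 0, innov_sd),
                                    config$ar_phi, method = "recursive"))
  hr_min <- clamp(mu + week_effect + circadian +
                    config$hr_activity_gain * steps + noise, 30, 220)

  per_min <- 60L %/% config$hr_interval_s
  hr_samples <- clamp(rep(hr_min, each = per_min) +
                        stats::rnorm(n_min * per_min, 0, 1), 20, 250)
  epoch <- cohort_epoch()
  hr_ts <- epoch + rep(minute * 60, each = per_min) +
    rep(seq(0L, 59L, by = config$hr_interval_s), times = n_min)
  step_ts <- epoch + minute * 60

  out <- rbind(
    data.frame(patient_id = profile$patient_id, timestamp = hr_ts,
               channel = "hr", value = hr_samples, stringsAsFactors = FALSE),
    data.frame(patient_id = profile$patient_id, timestamp = step_ts,
               channel = "steps", value = as.numeric(steps),
               stringsAsFactors = FALSE)
  )
  out[order(out$timestamp, out$channel), , drop = FALSE]
}

#' Delete contiguous device-off gaps from a raw stream
#'
#' Emulates periods in which the device was not worn or data were not
#' received: whole calendar minutes are deleted in contiguous gaps with
#' geometrically distributed lengths (mean `mean_gap_min`), removing both the
#' heart-rate and step channel, until the deleted fraction of the recording's
#' minutes matches `missing_frac` (the final gap is trimmed, so the realized
#' fraction is within one minute of the target).
#'
#' @param stream A long-format stream data frame (see [generate_cohort()]).
#' @param missing_frac Target deleted fraction of minutes, in `[0, 1)`.
#' @param mean_gap_min Mean gap length in minutes (>= 1).
#' @param seed Integer seed controlling gap placement.
#' @return The stream with records in deleted minutes removed. With
#'   `missing_frac = 0` the stream is returned unchanged.
#' @examples
#' co <- generate_cohort(cohort_config(n_patients = 2, n_weeks = 1,
#'                                     missing_frac = 0, seed = 3))
#' s <- apply_missingness(co$streams[[1]], 0.2, 60, seed = 9)
#' nrow(s) < nrow(co$streams[[1]])
#' @export
apply_missingness <- function(stream, missing_frac, mean_gap_min, seed) {
  if (missing_frac < 0 || missing_frac >= 1) {
    stop("missing_frac must lie in [0, 1)", call. = FALSE)
  }
  if (mean_gap_min < 1) stop("mean_gap_min must be >= 1", call. = FALSE)
  if (missing_frac == 0) return(stream)
  set.seed(as.integer(seed))
  t0 <- min(stream$timestamp)
  minute_index <- as.integer(floor(as.numeric(difftime(stream$timestamp, t0,
                                                       units = "mins")))) + 1L
  n_min <- max(minute_index)
  target <- as.integer(round(missing_frac * n_min))
  deleted <- logical(n_min)
  n_deleted <- 0L
  while (n_deleted < target) {
    start <- sample.int(n_min, 1L)
    len <- stats::rgeom(1L, 1 / mean_gap_min) + 1L
    gap <- start:min(n_min, start + len - 1L)
    gap <- gap[!deleted[gap]]
    if (length(gap) > target - n_deleted) {
      gap <- gap[seq_len(target - n_deleted)]
    }
    deleted[gap] <- TRUE
    n_deleted <- n_deleted + length(gap)
  }
  stream[!deleted[minute_index], , drop = FALSE]
}

#' Assign end-of-trial NYHA classes linked to observed activity
#'
#' Draws `nyha_final` for each patient from an ordinal latent-variable model
#' \eqn{latent_i = -\beta\, z(\bar{s}_i) + \epsilon_i}, where
#' \eqn{\bar{s}_i} is the patient's mean weekly step total, \eqn{z} is
#' cohort standardization, \eqn{\beta} is `config$nyha_activity_coef` and
#' \eqn{\epsilon \sim N(0,1)}. Thresholds are scaled by the latent standard
#' deviation so the marginal class distribution stays near 2% I, 70% II,
#' 26% III, 2% IV regardless of \eqn{\beta}. Higher activity gives
#' stochastically lower (better) class; \eqn{\beta = 0} makes the labels
#' independent of activity.
#'
#' @param profiles Profile data frame from [generate_cohort()].
#' @param streams Named list of raw streams (step records are summed to get
#'   weekly activity; pooling is not required).
#' @param config The [cohort_config()]; uses `nyha_activity_coef` and `seed`.
#' @return `profiles` with `nyha_final` filled in.
#' @export
assign_nyha_labels <- function(profiles, streams, config) {
  if (length(streams) == 0 || any(vapply(streams, nrow, 0L) == 0L)) {
    stop("streams must be non-empty for every patient", call. = FALSE)
  }
  mean_weekly <- vapply(streams, function(s) {
    st <- s[s$channel == "steps", ]
    span_wk <- max(1 / 10080,
                   as.numeric(difftime(max(s$timestamp), min(s$timestamp),
                                       units = "mins")) / 10080)
    sum(st$value) / span_wk
  }, 0)
  mean_weekly <- mean_weekly[profiles$patient_id]
  z <- scale(mean_weekly)[, 1]
  if (!is.finite(stats::sd(mean_weekly)) || stats::sd(mean_weekly) == 0) {
    z <- rep(0, nrow(profiles))
  }
  set.seed(derive_seed(config$seed, 2L))
  beta <- config$nyha_activity_coef
  latent <- -beta * z + stats::rnorm(nrow(profiles))
  cuts <- stats::qnorm(c(0.02, 0.72, 0.98)) * sqrt(1 + beta^2)
  profiles$nyha_final <- factor(
    c("I", "II", "III", "IV")[findInterval(latent, cuts) + 1L],
    levels = c("I", "II", "III", "IV")
  )
  profiles
}

#' Simulate weekly summaries directly from the cohort model
#'
#' Fast path for repeated-measures simulation studies: draws the weekly mean
#' heart rates and step totals implied by the generative model of
#' [generate_cohort()] without materializing minute-level streams. Weekly
#' mean heart rate for patient \eqn{i}, week \eqn{w} is
#' \eqn{\mu + \delta\,[digoxin] + b_i + u_{iw} + g\bar{s}_{iw} + m^{-1/2}e},
#' with the same variance components (so weekly means are exchangeable with
#' correlation `week_correlation`), activity contribution through the mean
#' steps per minute, and the residual of averaging \eqn{m} nonmissing minutes
#' of AR noise. The circadian term averages out over whole weeks.
#'
#' @param config A [cohort_config()].
#' @return A list with `profiles` and `summaries` (columns `patient_id`,
#'   `week_index`, `mean_hr_bpm`, `total_steps`, `nonmissing_minutes`,
#'   `activity_category`), ready for [fit_gee_exchangeable()].
#' @examples
#' wk <- simulate_weekly_cohort(cohort_config(n_patients = 10, seed = 2))
#' head(wk$summaries)
#' @export
simulate_weekly_cohort <- function(config) {
  validate_cohort_config(config)
  profiles <- draw_profiles(config)
  n <- config$n_patients
  w <- config$n_weeks
  set.seed(derive_seed(config$seed, 3L))
  vc <- weekly_variance_components(config)
  b <- stats::rnorm(n, 0, vc$intercept_sd)
  mu_i <- config$baseline_hr_bpm +
    config$treatment_effect_bpm * (profiles$arm == "digoxin") + b

  base_weekly <- if (config$night_gate) 26880 else 40320
  mean_wk_steps <- base_weekly * profiles$activity_level
  total_steps <- round(pmax(0, stats::rnorm(n * w, rep(mean_wk_steps, each = w),
                                            rep(0.1 * mean_wk_steps, each = w))))
  m <- max(1, round(10080 * (1 - config$missing_frac)))
  mean_hr <- rep(mu_i, each = w) +
    stats::rnorm(n * w, 0, vc$week_sd) +
    config$hr_activity_gain * total_steps / 10080 +
    stats::rnorm(n * w, 0, config$within_patient_sd_bpm / sqrt(m))

  summaries <- data.frame(
    patient_id = rep(profiles$patient_id, each = w),
    week_index = rep(seq_len(w), times = n),
    mean_hr_bpm = mean_hr,
    total_steps = total_steps,
    nonmissing_minutes = m,
    activity_category = activity_category(total_steps),
    stringsAsFactors = FALSE
  )
  mean_weekly <- tapply(summaries$total_steps, summaries$patient_id, mean)
  z <- if (stats::sd(mean_weekly) > 0) scale(mean_weekly[profiles$patient_id])[, 1]
       else rep(0, n)
  beta <- config$nyha_activity_coef
  latent <- -beta * z + stats::rnorm(n)
  cuts <- stats::qnorm(c(0.02, 0.72, 0.98)) * sqrt(1 + beta^2)
  profiles$nyha_final <- factor(
    c("I", "II", "III", "IV")[findInterval(latent, cuts) + 1L],
    levels = c("I", "II", "III", "IV")
  )
  list(profiles = profiles, summaries = summaries)
}
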