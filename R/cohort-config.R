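#' Configuration for a synthetic wearables cohort
#'
#' Collects the generative parameters for a two-arm randomized cohort of
#' patients with permanent atrial fibrillation wearing a wrist device that
#' reports heart rate every `hr_interval_s` seconds and step counts once per
#' minute. The heart-rate model for patient \eqn{i} at minute \eqn{t} is
#' \deqn{hr_i(t) = \mu + \delta\,[arm_i = digoxin] + b_i + u_{i,w(t)} +
#'   A\cos(2\pi (h(t)-16)/24) + g \cdot steps_i(t) + e_i(t)}
#' with patient intercept \eqn{b_i}, week-level perturbation \eqn{u_{iw}},
#' circadian term peaking at 16:00, activity gain \eqn{g} (bpm per step/min)
#' and AR(1) minute noise \eqn{e}. The variances of \eqn{b} and \eqn{u} are
#' parameterized through `between_patient_sd_bpm` and `week_correlation`:
#' weekly mean heart rates are exchangeable with correlation
#' `week_correlation`, the compound-symmetry structure assumed by the
#' downstream repeated-measures estimator.
#'
#' Defaults mirror an older, multimorbid AF cohort: about 50 patients
#' followed for 20 weeks, cohort heart-rate mean near 76 bpm, weekly-mean
#' standard deviation near 6 bpm with exchangeable correlation 0.91, and
#' weekly step totals spanning the CDC activity bands (below 15,000 through
#' above 30,000 steps per week).
#'
#' @param n_patients Number of patients (at least 2; cross-patient channel
#'   scrambling is undefined for a single patient).
#' @param n_weeks Weeks of wearable follow-up per patient.
#' @param baseline_hr_bpm Cohort mean heart rate in the reference
#'   (beta-blocker) arm, bpm.
#' @param treatment_effect_bpm True arm difference (digoxin minus
#'   beta-blocker), bpm. Zero reproduces a null trial.
#' @param between_patient_sd_bpm Standard deviation of stable patient
#'   heart-rate intercepts, bpm.
#' @param within_patient_sd_bpm Marginal standard deviation of the AR(1)
#'   minute-level noise, bpm.
#' @param week_correlation Exchangeable correlation of weekly mean heart
#'   rates, in `[0, 1)`.
#' @param hr_activity_gain Heart-rate increase per step per minute
#'   (bpm / (steps/min)).
#' @param circadian_amplitude_bpm Amplitude of the sinusoidal circadian
#'   heart-rate term, bpm (acrophase 16:00).
#' @param ar_phi AR(1) coefficient of the minute-level noise.
#' @param missing_frac Target fraction of minutes deleted by device-off /
#'   connectivity gaps, in `[0, 1)`.
#' @param mean_gap_min Mean length (minutes) of a missingness gap.
#' @param nyha_activity_coef Strength of the latent link from standardized
#'   weekly activity to end-of-trial NYHA class (0 = no link).
#' @param night_gate If `TRUE`, step counts are gated to ~0 between 23:00
#'   and 07:00 (sleep); disable to produce streams with no time-of-day
#'   structure in the activity channel.
#' @param hr_interval_s Native heart-rate sampling interval, seconds.
#' @param seed Integer seed; every stochastic step derives from it.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_patients = 4, n_weeks = 1, seed = 7)
#' cfg$week_correlation
#' @export
cohort_config <- function(n_patients = 50,
                          n_weeks = 20,
                          baseline_hr_bpm = 76,
                          treatment_effect_bpm = 0,
                          between_patient_sd_bpm = 6 * sqrt(0.91),
                          within_patient_sd_bpm = 8,
                          week_correlation = 0.91,
                          hr_activity_gain = 0.15,
                          circadian_amplitude_bpm = 3,
                          ar_phi = 0.8,
                          missing_frac = 0.15,
                          mean_gap_min = 60,
                          nyha_activity_coef = 1.5,
                          night_gate = TRUE,
                          hr_interval_s = 10,
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_weeks = as.integer(n_weeks),
    baseline_hr_bpm = baseline_hr_bpm,
    treatment_effect_bpm = treatment_effect_bpm,
    between_patient_sd_bpm = between_patient_sd_bpm,
    within_patient_sd_bpm = within_patient_sd_bpm,
    week_correlation = week_correlation,
    hr_activity_gain = hr_activity_gain,
    circadian_amplitude_bpm = circadian_amplitude_bpm,
    ar_phi = ar_phi,
    missing_frac = missing_frac,
    mean_gap_min = as.integer(mean_gap_min),
    nyha_activity_coef = nyha_activity_coef,
    night_gate = isTRUE(night_gate),
    hr_interval_s = as.integer(hr_interval_s),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_patients < 2L) {
    stop("n_patients must be >= 2: cross-patient scrambling needs at least two patients",
         call. = FALSE)
  }
  if (cfg$n_weeks < 1L) stop("n_weeks must be >= 1", call. = FALSE)
  for (nm in c("between_patient_sd_bpm", "within_patient_sd_bpm",
               "circadian_amplitude_bpm")) {
    if (cfg[[nm]] < 0) stop(sprintf("%s must be >= 0", nm), call. = FALSE)
  }
  if (cfg$week_correlation < 0 || cfg$week_correlation >= 1) {
    stop("week_correlation must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$missing_frac < 0 || cfg$missing_frac >= 1) {
    stop("missing_frac must lie in [0, 1)", call. = FALSE)
  }
  if (abs(cfg$ar_phi) >= 1) stop("ar_phi must lie in (-1, 1)", call. = FALSE)
  if (!is.finite(cfg$nyha_activity_coef)) {
    stop("nyha_activity_coef must be finite", call. = FALSE)
  }
  if (cfg$mean_gap_min < 1L) stop("mean_gap_min must be >= 1", call. = FALSE)
  if (cfg$hr_interval_s < 1L || cfg$hr_interval_s > 60L ||
      60L %% cfg$hr_interval_s != 0L) {
    stop("hr_interval_s must divide 60", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d patients, %d weeks, arm effect %.2f bpm\n",
              x$n_patients, x$n_weeks, x$treatment_effect_bpm))
  cat(sprintf("  weekly-mean sd %.2f bpm (exchangeable rho %.2f), minute sd %.1f\n",
              sqrt(x$between_patient_sd_bpm^2 / max(x$week_correlation, 1e-12)),
              x$week_correlation, x$within_patient_sd_bpm))
  cat(sprintf("  activity gain %.3f bpm/(step/min), circadian %.1f bpm, missing %.0f%%\n",
              x$hr_activity_gain, x$circadian_amplitude_bpm, 100 * x$missing_frac))
  invisible(x)
}

# Variance components implied by the exchangeable weekly-mean correlation:
# corr(weekly means) = b_sd^2 / (b_sd^2 + week_sd^2). At rho = 0 the patient
# intercept vanishes and between_patient_sd_bpm is read as the weekly sd.
weekly_variance_components <- function(cfg) {
  rho <- cfg$week_correlation
  if (rho <= 0) {
    list(intercept_sd = 0, week_sd = cfg$between_patient_sd_bpm)
  } else {
    list(intercept_sd = cfg$between_patient_sd_bpm,
         week_sd = cfg$between_patient_sd_bpm * sqrt((1 - rho) / rho))
  }
}

# Derive a stream of distinct 31-bit seeds from a base seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483629)
}
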