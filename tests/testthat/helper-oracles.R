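# Independent brute-force oracles used to check the package implementations.

# F1 by direct confusion-matrix counting for one positive class.
f1_brute <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# AUROC by exhaustive concordant-pair counting (ties count 1/2).
auroc_brute <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Spearman rho via the classical no-ties formula 1 - 6 sum(d^2) / (n(n^2-1)).
spearman_brute <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Kruskal-Wallis H for two groups by the explicit rank formula (no ties).
kw_brute <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  r1 <- sum(r[seq_along(x)])
  r2 <- sum(r[length(x) + seq_along(y)])
  12 / (n * (n + 1)) * (r1^2 / length(x) + r2^2 / length(y)) - 3 * (n + 1)
}

# Generalized least squares by explicit dense matrix algebra.
gls_brute <- function(y, X, V) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

# Minimal toy stream: one patient, explicit records.
toy_stream <- function(patient_id = "T1", t0 = as.POSIXct("2019-01-07 00:00:00", tz = "UTC"),
                       hr_offsets_s = numeric(), hr_values = numeric(),
                       step_offsets_s = numeric(), step_values = numeric()) {
  rbind(
    if (length(hr_offsets_s))
      data.frame(patient_id = patient_id, timestamp = t0 + hr_offsets_s,
                 channel = "hr", value = hr_values, stringsAsFactors = FALSE),
    if (length(step_offsets_s))
      data.frame(patient_id = patient_id, timestamp = t0 + step_offsets_s,
                 channel = "steps", value = step_values,
                 stringsAsFactors = FALSE)
  )
}

# Small profile table for GEE design building.
toy_profiles <- function(ids, arms) {
  data.frame(patient_id = ids, arm = arms, age_years = 70, gender = "man",
             heart_failure = FALSE, nt_probnp_pg_ml = 1000, bmi_kg_m2 = 25,
             ecg_hr_bpm = 90, smw_distance_m = 300, smw_time_s = 360,
             smw_speed_m_s = 300 / 360, stringsAsFactors = FALSE)
}

toy_summaries <- function(ids, weeks, hr, steps = 1) {
  data.frame(patient_id = ids, week_index = weeks, mean_hr_bpm = hr,
             total_steps = steps, nonmissing_minutes = 10000,
             activity_category = activity_category(rep(steps,
                                                       length.out = length(ids))),
             stringsAsFactors = FALSE)
}

# Study-condition configs used across SSL tests: strong heart-rate/activity
# coupling versus fully decoupled channels.
coupled_config <- function(seed = 1, n_patients = 10, n_weeks = 2) {
  cohort_config(n_patients = n_patients, n_weeks = n_weeks,
                hr_activity_gain = 0.5, within_patient_sd_bpm = 2,
                circadian_amplitude_bpm = 3, missing_frac = 0.1,
                nyha_activity_coef = 3, seed = seed)
}

decoupled_config <- function(seed = 1, n_patients = 10, n_weeks = 2) {
  cohort_config(n_patients = n_patients, n_weeks = n_weeks,
                hr_activity_gain = 0, within_patient_sd_bpm = 2,
                circadian_amplitude_bpm = 0, night_gate = FALSE,
                missing_frac = 0.1, nyha_activity_coef = 0, seed = seed)
}

# Reduced network for training tests; the full architecture is exercised
# separately for its structural properties.
tiny_cnn_spec <- function() {
  cnn_spec(conv_filters = c(4L, 8L, 8L), kernel_size = 9L, batch_size = 64L)
}

# Hand-built window set (no generation / pooling) for bookkeeping tests.
make_window_set <- function(patients, n_per_patient, L = 24L,
                            available = TRUE, seed = 1,
                            start0 = as.POSIXct("2019-01-07 00:00:00",
                                                tz = "UTC")) {
  set.seed(seed)
  n <- length(patients) * n_per_patient
  values <- array(rnorm(n * L * 3, sd = 0.5), c(n, L, 3))
  values[, , 3] <- 0
  starts <- start0 + rep(seq_len(n_per_patient) - 1, length(patients)) * 4 * 3600
  index <- data.frame(
    patient_id = rep(patients, each = n_per_patient),
    window_index = rep(seq_len(n_per_patient), length(patients)),
    window_start = starts,
    hour_of_day = as.numeric(format(starts, "%H", tz = "UTC")),
    available = rep_len(available, n),
    stringsAsFactors = FALSE
  )
  structure(list(values = values, index = index, window_min = L),
            class = "window_set")
}
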