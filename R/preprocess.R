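#' Pool a raw sensor stream to per-minute series
#'
#' Applies the 1-minute pooling rule: heart-rate samples are averaged within
#' each calendar minute, step counts are summed. The result has one slot per
#' calendar minute from the first to the last record; minutes with no
#' heart-rate record are missing, and the mask channel is 1 wherever the
#' heart-rate minute or the step minute is missing (union rule), so a single
#' mask stays truthful for both value channels.
#'
#' @param stream Long-format data frame with columns `patient_id`,
#'   `timestamp`, `channel` (`"hr"`/`"steps"`), `value`.
#' @return A `minute_series` object: list with `patient_id`, `start`
#'   (POSIXct of the first minute), numeric vectors `hr_bpm` and `steps`
#'   (`NA` where missing), `mask` (0/1), and the per-channel missingness
#'   indicators `hr_missing`, `steps_missing`.
#' @examples
#' co <- generate_cohort(cohort_config(n_patients = 2, n_weeks = 1, seed = 5))
#' ms <- pool_to_minutes(co$streams[[1]])
#' mean(ms$mask)
#' @export
pool_to_minutes <- function(stream) {
  if (is.null(stream) || nrow(stream) == 0) {
    stop("cannot pool an empty stream", call. = FALSE)
  }
  if (any(!is.finite(stream$value))) {
    stop("stream contains non-finite values", call. = FALSE)
  }
  secs <- as.numeric(stream$timestamp)
  minute <- floor(secs / 60)
  m0 <- min(minute)
  idx <- as.integer(minute - m0) + 1L
  n_min <- max(idx)

  hr_rows <- stream$channel == "hr"
  hr_bpm <- rep(NA_real_, n_min)
  if (any(hr_rows)) {
    hi <- idx[hr_rows]
    sums <- rowsum(stream$value[hr_rows], hi)
    cnts <- rowsum(rep(1, sum(hr_rows)), hi)
    hr_bpm[as.integer(rownames(sums))] <- sums[, 1] / cnts[, 1]
  }
  steps <- rep(NA_real_, n_min)
  st_rows <- stream$channel == "steps"
  if (any(st_rows)) {
    si <- idx[st_rows]
    ssum <- rowsum(stream$value[st_rows], si)
    steps[as.integer(rownames(ssum))] <- ssum[, 1]
  }
  hr_missing <- is.na(hr_bpm)
  steps_missing <- is.na(steps)
  structure(
    list(patient_id = stream$patient_id[1],
         start = as.POSIXct(m0 * 60, origin = "1970-01-01", tz = "UTC"),
         hr_bpm = hr_bpm,
         steps = steps,
         mask = as.integer(hr_missing | steps_missing),
         hr_missing = hr_missing,
         steps_missing = steps_missing,
         normalized = FALSE),
    class = "minute_series"
  )
}

#' @export
print.minute_series <- function(x, ...) {
  cat(sprintf("<minute_series> %s: %d minutes from %s, %.1f%% masked%s\n",
              x$patient_id, length(x$hr_bpm), format(x$start),
              100 * mean(x$mask), if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalize a minute series with the patient's own statistics
#'
#' Heart rate is standardized to z-scores over the patient's nonmissing
#' minutes; step counts are scaled to `[0, 1]` by the patient's maximum
#' per-minute step count (with a `max(1, .)` guard so an all-zero step
#' channel stays zero). Missing minutes are filled with 0 in both value
#' channels -- the per-patient mean heart rate and zero steps, neutral under
#' these normalizations -- while the mask channel records where they were.
#'
#' @param series A `minute_series` from [pool_to_minutes()].
#' @return The normalized `minute_series` (`normalized = TRUE`).
#' @export
normalize_patient <- function(series) {
  stopifnot(inherits(series, "minute_series"))
  if (isTRUE(series$normalized)) stop("series is already normalized", call. = FALSE)
  obs <- !series$hr_missing
  if (sum(obs) < 2) stop("need >= 2 nonmissing heart-rate minutes", call. = FALSE)
  mu <- mean(series$hr_bpm[obs])
  sdv <- stats::sd(series$hr_bpm[obs])
  if (!is.finite(sdv) || sdv == 0) {
    stop("constant heart-rate series: z-score undefined (zero variance)",
         call. = FALSE)
  }
  hr <- (series$hr_bpm - mu) / sdv
  hr[series$hr_missing] <- 0
  max_steps <- max(1, series$steps[!series$steps_missing], na.rm = TRUE)
  st <- series$steps / max_steps
  st[series$steps_missing] <- 0
  series$hr_bpm <- hr
  series$steps <- st
  series$normalized <- TRUE
  series$hr_center <- mu
  series$hr_scale <- sdv
  series$steps_scale <- max_steps
  series
}

#' Extract staggered fixed-length windows for the convolutional model
#'
#' Cuts a normalized minute series into windows of `window_min` minutes
#' starting at offsets `0, stride_min, 2 * stride_min, ...`; for a series of
#' `T` minutes this yields `floor((T - window_min) / stride_min) + 1`
#' windows (none, without error, when `T < window_min`). Each window is a
#' `window_min x 3` slab of (z-scored heart rate, scaled steps, mask), and
#' is flagged `available` when its fraction of nonmissing heart-rate minutes
#' reaches `availability_threshold`.
#'
#' @param series A normalized `minute_series`.
#' @param window_min Window length in minutes (default 240, i.e. 4 h).
#' @param stride_min Stagger between consecutive window starts, minutes.
#' @param availability_threshold Minimum nonmissing heart-rate fraction for
#'   a window to count as available.
#' @return A `window_set`: list with `values` (array `n x window_min x 3`)
#'   and `index` (data frame: `patient_id`, `window_index`, `window_start`,
#'   `hour_of_day`, `available`).
#' @export
extract_windows <- function(series, window_min = 240L, stride_min = 60L,
                            availability_threshold = 0.5) {
  stopifnot(inherits(series, "minute_series"))
  if (!isTRUE(series$normalized)) {
    stop("extract_windows expects a normalized series; call normalize_patient() first",
         call. = FALSE)
  }
  T_len <- length(series$hr_bpm)
  n_win <- if (T_len < window_min) 0L
           else (T_len - window_min) %/% stride_min + 1L
  values <- array(0, dim = c(n_win, window_min, 3L))
  starts <- integer(n_win)
  avail <- logical(n_win)
  for (k in seq_len(n_win)) {
    from <- (k - 1L) * stride_min + 1L
    rng <- from:(from + window_min - 1L)
    values[k, , 1L] <- series$hr_bpm[rng]
    values[k, , 2L] <- series$steps[rng]
    values[k, , 3L] <- series$mask[rng]
    starts[k] <- from - 1L
    avail[k] <- mean(!series$hr_missing[rng]) >= availability_threshold
  }
  window_start <- series$start + starts * 60
  index <- data.frame(
    patient_id = rep(series$patient_id, n_win),
    window_index = seq_len(n_win),
    window_start = if (n_win) window_start else as.POSIXct(character(), tz = "UTC"),
    hour_of_day = if (n_win) as.numeric(format(window_start, "%H", tz = "UTC")) +
      as.numeric(format(window_start, "%M", tz = "UTC")) / 60 else numeric(),
    available = avail,
    stringsAsFactors = FALSE
  )
  structure(list(values = values, index = index, window_min = window_min),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d min (%d available) from %d patient(s)\n",
              nrow(x$index), x$window_min, sum(x$index$available),
              length(unique(x$index$patient_id))))
  invisible(x)
}

#' Concatenate window sets from several patients
#'
#' @param ... `window_set` objects (or a single list of them).
#' @return A combined `window_set`.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "window_set")) sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, TRUE, "window_set")))
  wm <- unique(vapply(sets, function(s) s$window_min, 0L))
  stopifnot(length(wm) == 1)
  n <- vapply(sets, function(s) nrow(s$index), 0L)
  values <- array(0, dim = c(sum(n), wm, 3L))
  at <- 0L
  for (s in sets) {
    if (nrow(s$index)) values[at + seq_len(nrow(s$index)), , ] <- s$values
    at <- at + nrow(s$index)
  }
  index <- do.call(rbind, lapply(sets, function(s) s$index))
  rownames(index) <- NULL
  structure(list(values = values, index = index, window_min = wm),
            class = "window_set")
}

subset_window_set <- function(ws, keep) {
  keep <- which(if (is.logical(keep)) keep else seq_len(nrow(ws$index)) %in% keep)
  structure(list(values = ws$values[keep, , , drop = FALSE],
                 index = ws$index[keep, , drop = FALSE],
                 window_min = ws$window_min),
            class = "window_set")
}

#' Weekly summaries of heart rate and activity
#'
#' Splits an (unnormalized) minute series into calendar weeks of 10,080
#' minutes indexed from the first device minute, keeping at most `max_weeks`
#' weeks. Weeks whose fraction of nonmissing heart-rate minutes falls below
#' `min_nonmissing_frac` are excluded. Each retained week reports the mean
#' heart rate over nonmissing minutes, the total step count, the count of
#' nonmissing heart-rate minutes, and the CDC activity band of the weekly
#' step total (see [activity_category()]).
#'
#' @param series A `minute_series` in original units.
#' @param max_weeks Maximum number of weeks to summarize.
#' @param min_nonmissing_frac Exclusion threshold on the heart-rate
#'   nonmissing fraction (relative to a full 10,080-minute week).
#' @return Data frame with columns `patient_id`, `week_index`,
#'   `mean_hr_bpm`, `total_steps`, `nonmissing_minutes`,
#'   `activity_category`.
#' @export
weekly_summaries <- function(series, max_weeks = 20L,
                             min_nonmissing_frac = 0.1) {
  stopifnot(inherits(series, "minute_series"))
  if (isTRUE(series$normalized)) {
    stop("weekly_summaries expects a series in original units", call. = FALSE)
  }
  wk_len <- 10080L
  T_len <- length(series$hr_bpm)
  n_weeks <- min(as.integer(max_weeks), ceiling(T_len / wk_len))
  rows <- vector("list", n_weeks)
  for (w in seq_len(n_weeks)) {
    rng <- ((w - 1L) * wk_len + 1L):min(w * wk_len, T_len)
    obs <- rng[!series$hr_missing[rng]]
    if (length(obs) / wk_len < min_nonmissing_frac) next
    steps_obs <- rng[!series$steps_missing[rng]]
    rows[[w]] <- data.frame(
      patient_id = series$patient_id,
      week_index = w,
      mean_hr_bpm = mean(series$hr_bpm[obs]),
      total_steps = sum(series$steps[steps_obs]),
      nonmissing_minutes = length(obs),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), week_index = integer(),
                      mean_hr_bpm = numeric(), total_steps = numeric(),
                      nonmissing_minutes = integer(), stringsAsFactors = FALSE)
  }
  out$activity_category <- activity_category(out$total_steps)
  rownames(out) <- NULL
  out
}

#' Spearman correlation of daytime heart rate and activity
#'
#' Bins a raw stream into `interval_s`-second intervals (heart rate averaged,
#' steps summed within a bin), keeps bins falling between `day_start` and
#' `day_end` hours that carry both channels, and returns the Spearman rank
#' correlation. Since step records arrive once per minute, each step record
#' pairs with the single sub-minute heart-rate bin it falls in. The returned
#' band follows the conventional interpretation used for these devices:
#' absolute correlation below 0.20 is `"very weak"`, 0.20-0.59 is
#' `"weak to moderate"`, 0.60 and above `"strong"`.
#'
#' @param stream Long-format raw stream (native cadence retained).
#' @param interval_s Pairing interval in seconds (default 10).
#' @param day_start,day_end Daytime limits in hours (default 07:00-23:00).
#' @return List with `rho`, `p_value`, `n_pairs`, `band`.
#' @export
daytime_correlation <- function(stream, interval_s = 10L, day_start = 7,
                                day_end = 23) {
  secs <- as.numeric(stream$timestamp)
  bin <- floor(secs / interval_s)
  hour <- (secs %% 86400) / 3600
  day <- hour >= day_start & hour < day_end

  hr_rows <- stream$channel == "hr" & day
  st_rows <- stream$channel == "steps" & day
  hr_by_bin <- tapply(stream$value[hr_rows], bin[hr_rows], mean)
  st_by_bin <- tapply(stream$value[st_rows], bin[st_rows], sum)
  common <- intersect(names(hr_by_bin), names(st_by_bin))
  if (length(common) < 3) {
    stop("need at least 3 paired daytime intervals", call. = FALSE)
  }
  x <- unname(hr_by_bin[common])
  y <- unname(st_by_bin[common])
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    stop("zero-variance ranks: correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(x, y, method = "spearman")
  pv <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE)$p.value)
  band <- if (abs(rho) < 0.20) "very weak"
          else if (abs(rho) < 0.60) "weak to moderate"
          else "strong"
  list(rho = rho, p_value = pv, n_pairs = length(common), band = band)
}

#' Pool, summarize and window a whole cohort
#'
#' Convenience wrapper running [pool_to_minutes()], [weekly_summaries()],
#' [normalize_patient()] and [extract_windows()] over every stream of a
#' cohort.
#'
#' @param streams Named list of raw streams.
#' @param max_weeks Passed to [weekly_summaries()].
#' @param window_min,stride_min,availability_threshold Passed to
#'   [extract_windows()].
#' @return List with `summaries` (row-bound data frame) and `windows`
#'   (combined `window_set`).
#' @export
preprocess_cohort <- function(streams, max_weeks = 20L, window_min = 240L,
                              stride_min = 60L, availability_threshold = 0.5) {
  summaries <- list()
  sets <- list()
  for (pid in names(streams)) {
    ms <- pool_to_minutes(streams[[pid]])
    summaries[[pid]] <- weekly_summaries(ms, max_weeks = max_weeks)
    norm <- normalize_patient(ms)
    sets[[pid]] <- extract_windows(norm, window_min = window_min,
                                   stride_min = stride_min,
                                   availability_threshold = availability_threshold)
  }
  list(summaries = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
       windows = bind_window_sets(sets))
}
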