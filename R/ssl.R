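window_bucket <- function(hour_of_day) as.integer(hour_of_day) %/% 4L

# First-week flag relative to each patient's first window.
first_week_flags <- function(index, days = 7) {
  t0 <- tapply(as.numeric(index$window_start), index$patient_id, min)
  as.numeric(index$window_start) < t0[index$patient_id] + days * 86400
}

#' Split a window set into first-week and later windows
#'
#' The first week of each patient's recording is reserved for embedding and
#' downstream prediction; all later windows feed the self-supervised task.
#'
#' @param windows A `window_set`.
#' @param days Length of the reserved leading period (default 7).
#' @return List with `first_week` and `rest` window sets.
#' @export
split_first_week <- function(windows, days = 7) {
  fw <- first_week_flags(windows$index, days)
  list(first_week = subset_window_set(windows, fw),
       rest = subset_window_set(windows, !fw))
}

#' Build the channel-scrambling auxiliary dataset
#'
#' For every available window, adds one scrambled counterpart whose
#' heart-rate channel comes from the original patient but whose step channel
#' is taken from a randomly chosen window of a *different* patient, so
#' original (label 1) and scrambled (label 0) samples are balanced 50/50.
#' Each pair shares the elementwise union of the two donors' masks, applied
#' to *both* the original and the scrambled member (value channels
#' zero-filled where the union mask is 1): the mask stays truthful for the
#' composite sample and the mask distribution is identical across classes,
#' so missingness density alone carries no label information and the task
#' can only be solved through the cross-channel temporal structure. With
#' `time_match = TRUE` (default) the step donor is drawn from the same 4-h
#' time-of-day bucket when possible, so circadian phase alone cannot solve
#' the discrimination task either.
#'
#' @param windows A `window_set` (only available windows are used).
#' @param seed Integer seed for donor pairing.
#' @param time_match Match donors on the 4-h time-of-day bucket.
#' @return A `scrambled_dataset`: list with `X` (array `2n x L x 3`), `y`
#'   (1 original / 0 scrambled) and `info` (per-sample `label`, `hr_donor`,
#'   `steps_donor`).
#' @export
build_scrambled_dataset <- function(windows, seed = 1L, time_match = TRUE) {
  stopifnot(inherits(windows, "window_set"))
  ws <- subset_window_set(windows, windows$index$available)
  n <- nrow(ws$index)
  if (n == 0) stop("no available windows", call. = FALSE)
  pids <- ws$index$patient_id
  if (length(unique(pids)) < 2) {
    stop("cross-patient scrambling needs windows from at least 2 patients",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  bucket <- window_bucket(ws$index$hour_of_day)
  donor <- integer(n)
  for (i in seq_len(n)) {
    cand <- which(pids != pids[i] & bucket == bucket[i])
    if (!length(cand)) cand <- which(pids != pids[i])
    donor[i] <- if (length(cand) == 1) cand else sample(cand, 1L)
  }
  L <- ws$window_min
  union_mask <- pmax(ws$values[, , 3L], ws$values[donor, , 3L])
  keep <- 1 - union_mask
  X <- array(0, c(2L * n, L, 3L))
  orig <- array(0, c(n, L, 3L))
  orig[, , 1L] <- ws$values[, , 1L] * keep
  orig[, , 2L] <- ws$values[, , 2L] * keep
  orig[, , 3L] <- union_mask
  X[seq_len(n), , ] <- orig
  scr <- array(0, c(n, L, 3L))
  scr[, , 1L] <- ws$values[, , 1L] * keep
  scr[, , 2L] <- ws$values[donor, , 2L] * keep
  scr[, , 3L] <- union_mask
  X[n + seq_len(n), , ] <- scr
  info <- data.frame(
    label = rep(c(1L, 0L), each = n),
    hr_donor = c(pids, pids),
    steps_donor = c(pids, pids[donor]),
    stringsAsFactors = FALSE
  )
  structure(list(X = X, y = info$label, info = info),
            class = "scrambled_dataset")
}

#' Train the scrambling discriminator with patient-level cross-validation
#'
#' Partitions patients into `folds` folds; for each fold, a CNN is trained
#' to discriminate original from scrambled windows built *only* from the
#' training patients' non-first-week windows (the held-out patients' windows
#' never enter the scrambling pool of their own model -- no leakage), while
#' a scrambled set from the held-out patients monitors over/underfitting and
#' drives early stopping.
#'
#' @param windows A `window_set` spanning the full recording of every
#'   patient (the first week is excluded from training internally).
#' @param spec A [cnn_spec()].
#' @param folds Number of patient folds (default 5, i.e. ~20% held out).
#' @param epochs,patience Passed to [cnn_train()].
#' @param seed Integer seed (fold assignment, scrambling, initialization,
#'   training).
#' @param time_match Passed to [build_scrambled_dataset()].
#' @return An `ssl_fit`: per-fold `models`, `fold_assignment` (data frame
#'   `patient_id`, `fold`), and `states` (fold index, train/held-out
#'   patients, epochs run, history, held-out accuracy).
#' @export
train_discriminator <- function(windows, spec = cnn_spec(), folds = 5L,
                                epochs = 200L, patience = 10L, seed = 1L,
                                time_match = TRUE) {
  stopifnot(inherits(windows, "window_set"))
  avail <- windows$index$available
  patients <- sort(unique(windows$index$patient_id[avail]))
  if (length(patients) < folds) {
    stop("fewer patients than folds", call. = FALSE)
  }
  if (length(patients) < 2L * folds) {
    stop("need at least 2 patients per fold for held-out scrambling",
         call. = FALSE)
  }
  set.seed(derive_seed(seed, 5L))
  fold_of <- stats::setNames(
    sample(rep(seq_len(folds), length.out = length(patients))), patients)
  rest <- split_first_week(windows)$rest

  models <- vector("list", folds)
  states <- vector("list", folds)
  for (k in seq_len(folds)) {
    train_p <- patients[fold_of != k]
    held_p <- patients[fold_of == k]
    tr <- build_scrambled_dataset(
      subset_window_set(rest, rest$index$patient_id %in% train_p),
      seed = derive_seed(seed, 10L + k), time_match = time_match)
    va <- build_scrambled_dataset(
      subset_window_set(rest, rest$index$patient_id %in% held_p),
      seed = derive_seed(seed, 30L + k), time_match = time_match)
    model <- build_cnn(spec, input_len = windows$window_min,
                       seed = derive_seed(seed, 50L + k))
    model <- cnn_train(model, tr$X, tr$y, va$X, va$y, epochs = epochs,
                       patience = patience, seed = derive_seed(seed, 70L + k))
    pv <- cnn_predict(model, va$X)
    models[[k]] <- model
    states[[k]] <- list(fold_index = k, train_patients = train_p,
                        heldout_patients = held_p,
                        epochs_run = model$epochs_run,
                        history = model$history,
                        heldout_loss = cnn_loss(pv, va$y),
                        heldout_accuracy = mean((pv > 0.5) == (va$y == 1)))
  }
  structure(list(models = models,
                 fold_assignment = data.frame(patient_id = patients,
                                              fold = unname(fold_of),
                                              stringsAsFactors = FALSE),
                 states = states, spec = spec,
                 window_min = windows$window_min),
            class = "ssl_fit")
}

#' @export
print.ssl_fit <- function(x, ...) {
  acc <- vapply(x$states, function(s) s$heldout_accuracy, 0)
  cat(sprintf("<ssl_fit> %d folds over %d patients; held-out accuracy %s\n",
              length(x$models), nrow(x$fold_assignment),
              paste(sprintf("%.2f", acc), collapse = " / ")))
  invisible(x)
}

#' Embed each patient's first week with one trained model
#'
#' Runs the model with dropout and the classification head removed over each
#' patient's available first-week windows and averages the post-pooling
#' vectors (an unweighted mean, so the result is invariant to window order).
#' Patients with no available first-week window are excluded with a message,
#' mirroring the eligibility rule for the downstream prediction task.
#'
#' @param model A trained `afw_cnn`.
#' @param windows A `window_set` restricted to first-week windows (see
#'   [split_first_week()]).
#' @return Data frame with `patient_id`, `n_windows_used` and embedding
#'   columns `e1..eD`.
#' @export
embed_patient_first_week <- function(model, windows) {
  stopifnot(inherits(model, "afw_cnn"), inherits(windows, "window_set"))
  ws <- subset_window_set(windows, windows$index$available)
  all_p <- unique(windows$index$patient_id)
  have <- unique(ws$index$patient_id)
  dropped <- setdiff(all_p, have)
  if (length(dropped)) {
    message("excluded (no available first-week windows): ",
            paste(dropped, collapse = ", "))
  }
  if (!length(have)) stop("no patient has available first-week windows",
                          call. = FALSE)
  emb <- cnn_embed(model, ws$values)
  out <- lapply(have, function(pid) {
    rows <- ws$index$patient_id == pid
    v <- colMeans(emb[rows, , drop = FALSE])
    cbind(data.frame(patient_id = pid, n_windows_used = sum(rows),
                     stringsAsFactors = FALSE),
          as.data.frame(t(stats::setNames(v, paste0("e", seq_along(v))))))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Out-of-fold first-week embeddings for a whole cohort
#'
#' Embeds each patient's first week with the model from the fold in which
#' that patient was held out, so no patient is embedded by a model whose
#' scrambling/training pool contained their own windows. Each eligible
#' patient appears exactly once.
#'
#' @param fit An `ssl_fit` from [train_discriminator()].
#' @param first_week_windows A `window_set` of first-week windows.
#' @return Data frame as in [embed_patient_first_week()], plus a `fold`
#'   column.
#' @export
ssl_oof_embeddings <- function(fit, first_week_windows) {
  stopifnot(inherits(fit, "ssl_fit"))
  out <- list()
  for (k in seq_along(fit$models)) {
    held <- fit$states[[k]]$heldout_patients
    ws_k <- subset_window_set(first_week_windows,
                              first_week_windows$index$patient_id %in% held)
    if (!nrow(ws_k$index) || !any(ws_k$index$available)) next
    emb <- embed_patient_first_week(fit$models[[k]], ws_k)
    emb$fold <- k
    out[[k]] <- emb
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
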