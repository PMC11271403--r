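#' F1 score of class predictions
#'
#' Harmonic mean of precision and recall. `averaging = "binary"` scores the
#' positive class only; `"macro"` averages per-class F1 over the classes
#' present in the truth; `"weighted"` weights that average by class support.
#' The zero-division convention is 0 (a class never predicted, or absent
#' from the truth, contributes an F1 of 0).
#'
#' @param truth Vector (or factor) of true classes.
#' @param predicted Vector of predicted classes, same length.
#' @param averaging `"binary"`, `"macro"` or `"weighted"`.
#' @param positive Positive class for binary averaging (default: the last
#'   factor level, or the largest value).
#' @return F1 in `[0, 1]`.
#' @examples
#' f1_score(c(1, 1, 1, 1, 1, 0, 0), c(1, 1, 1, 0, 0, 1, 0), positive = 1)
#' @export
f1_score <- function(truth, predicted,
                     averaging = c("binary", "macro", "weighted"),
                     positive = NULL) {
  averaging <- match.arg(averaging)
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  one <- function(cls) {
    tp <- sum(truth == cls & predicted == cls)
    fp <- sum(truth != cls & predicted == cls)
    fn <- sum(truth == cls & predicted != cls)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  if (averaging == "binary") {
    if (is.null(positive)) positive <- sort(unique(truth))[length(unique(truth))]
    return(one(as.character(positive)))
  }
  classes <- sort(unique(truth))
  per <- vapply(classes, one, 0)
  if (averaging == "macro") mean(per)
  else sum(per * table(truth)[classes] / length(truth))
}

#' Rank-based AUROC
#'
#' Mann-Whitney estimate with midrank tie correction: the probability that a
#' randomly chosen positive receives a higher score than a randomly chosen
#' negative (ties counting one half).
#'
#' @param labels Binary truth (0/1, logical, or 2-level factor where the
#'   second level is positive).
#' @param scores Numeric scores, higher = more positive.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
#' @export
auroc <- function(labels, scores) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  y <- as.integer(labels != 0)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap percentile confidence interval for a prediction metric
#'
#' Resamples patients with replacement `n_boot` times and returns the
#' percentile 2.5/97.5 interval of the metric. Degenerate resamples in
#' which the truth contains a single class are skipped and counted.
#'
#' @param truth,predicted Vectors as in [f1_score()] (one entry per
#'   patient).
#' @param metric Function `(truth, predicted) -> numeric`; default binary
#'   [f1_score()].
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return List with `lo`, `hi`, `n_used`, `n_degenerate`.
#' @export
bootstrap_ci <- function(truth, predicted, metric = NULL, n_boot = 2000L,
                         seed = 1L, level = 0.95) {
  n <- length(truth)
  if (n < 2) stop("need at least 2 patients", call. = FALSE)
  if (is.null(metric)) metric <- function(t, p) f1_score(t, p)
  set.seed(as.integer(seed))
  vals <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(as.character(truth[idx]))) < 2) next
    vals[b] <- tryCatch(metric(truth[idx], predicted[idx]),
                        error = function(e) NA_real_)
  }
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("all bootstrap resamples were degenerate",
                          call. = FALSE)
  a <- (1 - level) / 2
  q <- stats::quantile(vals, c(a, 1 - a), names = FALSE, type = 7)
  list(lo = q[1], hi = q[2], n_used = length(vals),
       n_degenerate = n_boot - length(vals))
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Chance-level F1 under label permutation
#'
#' Expected F1 when the predicted labels are a uniformly random permutation
#' of the true labels: the reproducible surrogate for "chance" performance
#' with the observed class frequencies. Exact enumeration of all
#' permutations is used for small inputs (n <= 7), Monte-Carlo otherwise.
#'
#' @param labels Vector of true classes (>= 2 distinct classes).
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param seed Integer seed.
#' @param averaging,positive Passed to [f1_score()].
#' @return Expected F1.
#' @examples
#' chance_f1(c(1, 1, 1, 0))  # exact: 0.75
#' @export
chance_f1 <- function(labels, n_perm = 10000L, seed = 1L,
                      averaging = "binary", positive = NULL) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("need at least 2 classes", call. = FALSE)
  }
  n <- length(labels)
  if (n <= 7) {
    pm <- all_perms(n)
    mean(apply(pm, 1, function(ix) {
      f1_score(labels, labels[ix], averaging = averaging, positive = positive)
    }))
  } else {
    set.seed(as.integer(seed))
    mean(vapply(seq_len(n_perm), function(b) {
      f1_score(labels, sample(labels), averaging = averaging,
               positive = positive)
    }, 0))
  }
}

#' Permutation test of F1 against chance
#'
#' One-sided p-value for the hypothesis that the observed F1 exceeds what a
#' random assignment of the same predicted labels would achieve, using the
#' add-one permutation estimator.
#'
#' @param truth,predicted Vectors as in [f1_score()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param averaging,positive Passed to [f1_score()].
#' @return List with `f1`, `chance`, `p_value`.
#' @export
f1_permutation_test <- function(truth, predicted, n_perm = 1000L, seed = 1L,
                                averaging = "binary", positive = NULL) {
  obs <- f1_score(truth, predicted, averaging = averaging,
                  positive = positive)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(b) {
    f1_score(truth, sample(predicted), averaging = averaging,
             positive = positive)
  }, 0)
  list(f1 = obs, chance = mean(perm),
       p_value = (1 + sum(perm >= obs)) / (1 + n_perm))
}

#' Patient-level paired comparison of two models
#'
#' Paired bootstrap of the F1 difference: patients are resampled with
#' replacement jointly for both models, giving the distribution of
#' `delta_f1 = F1(a) - F1(b)`; the two-sided p-value is
#' `min(1, 2 * min(P(delta <= 0), P(delta >= 0)))`. Antisymmetric in the
#' two models by construction.
#'
#' @param preds_a,preds_b Prediction data frames with columns `patient_id`,
#'   `true_class`, `predicted_class` (as returned by
#'   [fit_ridge_logistic()]); the patient sets must coincide.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param positive Positive class for the binary F1.
#' @return List with `delta_f1`, `p_value`, `n_boot_used`, `method`.
#' @export
compare_models_paired <- function(preds_a, preds_b, n_boot = 10000L,
                                  seed = 1L, positive = NULL) {
  if (!setequal(preds_a$patient_id, preds_b$patient_id)) {
    stop("the two models must be evaluated on the same patients",
         call. = FALSE)
  }
  b <- preds_b[match(preds_a$patient_id, preds_b$patient_id), , drop = FALSE]
  truth <- as.character(preds_a$true_class)
  pa <- as.character(preds_a$predicted_class)
  pb <- as.character(b$predicted_class)
  f1 <- function(t, p) f1_score(t, p, positive = positive)
  delta_obs <- f1(truth, pa) - f1(truth, pb)
  set.seed(as.integer(seed))
  n <- length(truth)
  deltas <- rep(NA_real_, n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(truth[idx])) < 2) next
    deltas[i] <- f1(truth[idx], pa[idx]) - f1(truth[idx], pb[idx])
  }
  deltas <- deltas[!is.na(deltas)]
  if (!length(deltas)) stop("all bootstrap resamples were degenerate",
                            call. = FALSE)
  p <- min(1, 2 * min(mean(deltas <= 0), mean(deltas >= 0)))
  list(delta_f1 = delta_obs, p_value = p, n_boot_used = length(deltas),
       method = "paired patient-level bootstrap of the F1 difference")
}
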