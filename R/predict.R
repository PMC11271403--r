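#' Assemble a feature set for NYHA-class prediction
#'
#' Three feature sets are compared: `"wearable"` (the CNN embedding
#' dimensions, e.g. 32 columns), `"conventional"` (ECG heart rate plus the
#' 6-minute-walk distance, time and speed, 4 columns), and
#' `"wearable_plus_clinical"` (embedding plus age, gender indicator
#' (woman = 1) and BMI). Column order is fixed as listed. Patients lacking
#' an embedding are excluded with a message; standardization is deferred to
#' the fit so it can use training-fold statistics only.
#'
#' @param profiles Patient profile data frame.
#' @param embeddings Embedding data frame from [ssl_oof_embeddings()] (or
#'   `NULL` for the conventional set).
#' @param which One of `"wearable"`, `"conventional"`,
#'   `"wearable_plus_clinical"`.
#' @return A `feature_set`: list with `name`, `x` (patients x features
#'   matrix), `feature_names`, `patient_id`.
#' @export
make_features <- function(profiles, embeddings = NULL,
                          which = c("wearable", "conventional",
                                    "wearable_plus_clinical")) {
  which <- match.arg(which)
  if (which != "conventional") {
    if (is.null(embeddings)) stop("embeddings required for wearable sets",
                                  call. = FALSE)
    missing_emb <- setdiff(profiles$patient_id, embeddings$patient_id)
    if (length(missing_emb)) {
      message("excluded (no embedding): ", paste(missing_emb, collapse = ", "))
    }
    keep <- profiles$patient_id %in% embeddings$patient_id
  } else {
    keep <- rep(TRUE, nrow(profiles))
  }
  prof <- profiles[keep, , drop = FALSE]
  ecols <- grep("^e[0-9]+$", names(embeddings), value = TRUE)
  x <- switch(which,
    wearable = {
      emb <- embeddings[match(prof$patient_id, embeddings$patient_id), ecols,
                        drop = FALSE]
      as.matrix(emb)
    },
    conventional = as.matrix(prof[, c("ecg_hr_bpm", "smw_distance_m",
                                      "smw_time_s", "smw_speed_m_s")]),
    wearable_plus_clinical = {
      emb <- embeddings[match(prof$patient_id, embeddings$patient_id), ecols,
                        drop = FALSE]
      cbind(as.matrix(emb),
            age = prof$age_years,
            gender_woman = as.numeric(prof$gender == "woman"),
            bmi = prof$bmi_kg_m2)
    })
  rownames(x) <- prof$patient_id
  structure(list(name = which, x = x, feature_names = colnames(x),
                 patient_id = prof$patient_id),
            class = "feature_set")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Ridge-penalized logistic regression by Newton-Raphson on (possibly
# smoothed, i.e. fractional) targets. X must already include an intercept
# column, which is never penalized.
ridge_logistic_irls <- function(X, y_smooth, l2, max_iter = 50L, tol = 1e-10) {
  p <- ncol(X)
  pen <- c(0, rep(2 * l2, p - 1L))
  w <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% w)
    mu <- sigmoid(eta)
    grad <- crossprod(X, mu - y_smooth) + pen * w
    Wd <- pmax(mu * (1 - mu), 1e-6)
    H <- crossprod(X, X * Wd) + diag(pen, p)
    step <- solve(H, grad)
    w <- w - as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  w
}

log_loss <- function(y, p) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' Ridge logistic prediction of end-of-trial NYHA class
#'
#' Binarizes NYHA (class I/II, coded 0, versus III/IV, coded 1 -- the
#' clinically meaningful split between slight and marked limitation),
#' applies label smoothing `y' = y (1 - eps) + eps / 2`, and fits
#' L2-penalized logistic regression with patient-level `cv_folds`-fold
#' cross-validation: every patient receives an out-of-fold prediction from a
#' model that never saw them, with features standardized using
#' training-fold statistics only. When `l2` is `NULL` the penalty is chosen
#' from `c(0.01, 0.1, 1, 10)` by inner 3-fold log-loss on each training
#' fold.
#'
#' @param features A `feature_set` from [make_features()].
#' @param labels Factor of NYHA classes (levels among I-IV), aligned with
#'   `features$patient_id` (or a named factor).
#' @param l2 Ridge penalty, or `NULL` for inner-loop selection.
#' @param eps_smooth Label-smoothing epsilon in `[0, 1]`.
#' @param cv_folds Outer cross-validation folds.
#' @param seed Integer seed for fold assignment.
#' @return List with `predictions` (data frame: `patient_id`, `true_class`,
#'   `predicted_class`, `predicted_probability` of the positive III+ class),
#'   `fit` (weights refit on all data, chosen `l2`, `eps_smooth`), and
#'   `cv_scheme`.
#' @export
fit_ridge_logistic <- function(features, labels, l2 = NULL, eps_smooth = 0.1,
                               cv_folds = 5L, seed = 1L) {
  stopifnot(inherits(features, "feature_set"))
  if (!is.null(names(labels))) labels <- labels[features$patient_id]
  stopifnot(length(labels) == length(features$patient_id))
  y <- as.integer(as.character(labels) %in% c("III", "IV"))
  if (length(unique(y)) < 2) {
    stop("labels contain a single class after binarization", call. = FALSE)
  }
  n <- length(y)
  set.seed(as.integer(seed))
  cv_folds <- min(as.integer(cv_folds), min(table(y)))
  fold <- integer(n)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(cv_folds), length.out = length(idx)))
  }
  grid <- if (is.null(l2)) c(0.01, 0.1, 1, 10) else l2

  prob <- numeric(n)
  chosen <- numeric(cv_folds)
  for (k in seq_len(cv_folds)) {
    tr <- fold != k
    Xtr <- features$x[tr, , drop = FALSE]
    ctr <- colMeans(Xtr)
    str_ <- pmax(apply(Xtr, 2, stats::sd), 1e-8)
    Ztr <- cbind(1, scale(Xtr, ctr, str_))
    Zte <- cbind(1, scale(features$x[!tr, , drop = FALSE], ctr, str_))
    ys <- y[tr] * (1 - eps_smooth) + eps_smooth / 2
    lam <- if (length(grid) == 1) grid else {
      inner <- sample(rep(seq_len(3L), length.out = sum(tr)))
      losses <- vapply(grid, function(g) {
        mean(vapply(1:3, function(j) {
          it <- inner != j
          wj <- ridge_logistic_irls(Ztr[it, , drop = FALSE], ys[it], g)
          log_loss(y[tr][!it], sigmoid(as.numeric(Ztr[!it, , drop = FALSE] %*% wj)))
        }, 0))
      }, 0)
      grid[which.min(losses)]
    }
    chosen[k] <- lam
    w <- ridge_logistic_irls(Ztr, ys, lam)
    prob[!tr] <- sigmoid(as.numeric(Zte %*% w))
  }

  # reference fit on all data (reported weights)
  ctr <- colMeans(features$x)
  str_ <- pmax(apply(features$x, 2, stats::sd), 1e-8)
  Z <- cbind(1, scale(features$x, ctr, str_))
  lam_all <- stats::median(chosen)
  w_all <- ridge_logistic_irls(Z, y * (1 - eps_smooth) + eps_smooth / 2,
                               lam_all)
  preds <- data.frame(
    patient_id = features$patient_id,
    true_class = factor(ifelse(y == 1, "III+", "I/II"),
                        levels = c("I/II", "III+")),
    predicted_class = factor(ifelse(prob > 0.5, "III+", "I/II"),
                             levels = c("I/II", "III+")),
    predicted_probability = prob,
    stringsAsFactors = FALSE
  )
  list(predictions = preds,
       fit = list(weights = stats::setNames(w_all,
                                            c("(Intercept)",
                                              features$feature_names)),
                  l2 = lam_all, l2_per_fold = chosen,
                  eps_smooth = eps_smooth, feature_set = features$name),
       cv_scheme = sprintf("%d-fold patient-level CV, stratified by class",
                           cv_folds))
}
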