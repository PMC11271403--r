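#' Specify a repeated-measures model for the arm comparison
#'
#' The outcome is always the weekly mean heart rate and the exposure the
#' randomized arm (digoxin vs beta-blocker, coded digoxin = 1). Covariates
#' are drawn from the patient profile and weekly summaries with fixed
#' coding: `age` (years, centered at the cohort mean), `gender` (woman = 1),
#' `heart_failure` (diagnosis = 1), `nt_probnp` (log-transformed, since the
#' biomarker is right-skewed), and `weekly_steps` (weekly step total in
#' thousands, a week-varying activity adjustment).
#'
#' @param covariates Character vector from
#'   `c("age", "gender", "heart_failure", "nt_probnp", "weekly_steps")`.
#' @param subgroup Optional activity band (`"low"`, `"minimum_recommended"`,
#'   `"recommended"`): restrict the fit to week-level records in that band.
#' @return A `model_spec` list.
#' @export
model_spec <- function(covariates = character(), subgroup = NULL) {
  allowed <- c("age", "gender", "heart_failure", "nt_probnp", "weekly_steps")
  bad <- setdiff(covariates, allowed)
  if (length(bad)) {
    stop("unknown covariates: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(subgroup)) {
    subgroup <- match.arg(subgroup,
                          c("low", "minimum_recommended", "recommended"))
  }
  structure(list(outcome = "mean_hr_bpm", exposure = "arm",
                 covariates = covariates, subgroup = subgroup),
            class = "model_spec")
}

build_design <- function(summaries, profiles, spec) {
  dat <- merge(summaries, profiles, by = "patient_id", sort = FALSE)
  if (!is.null(spec$subgroup)) {
    dat <- dat[as.character(dat$activity_category) == spec$subgroup, ,
               drop = FALSE]
  }
  dat <- dat[order(dat$patient_id, dat$week_index), , drop = FALSE]
  if (nrow(dat) == 0) stop("no week-level records after filtering", call. = FALSE)
  X <- cbind("(Intercept)" = 1, arm_digoxin = as.numeric(dat$arm == "digoxin"))
  for (cv in spec$covariates) {
    col <- switch(cv,
      age = dat$age_years - mean(profiles$age_years),
      gender = as.numeric(dat$gender == "woman"),
      heart_failure = as.numeric(dat$heart_failure),
      nt_probnp = log(dat$nt_probnp_pg_ml),
      weekly_steps = dat$total_steps / 1000)
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- cv
  }
  list(y = dat$mean_hr_bpm, X = X, id = factor(dat$patient_id),
       arm = dat$arm[!duplicated(dat$patient_id)])
}

#' Gaussian GEE with exchangeable working correlation
#'
#' Fits an identity-link Gaussian marginal regression of weekly mean heart
#' rate on treatment arm (and covariates) accounting for repeated weekly
#' measurements within patients through an exchangeable (compound-symmetry)
#' working correlation. The correlation is estimated by the moment estimator
#' from Pearson residuals, the estimating equations are iterated to
#' convergence, and standard errors come from the robust sandwich
#' covariance, so inference is valid even if the working correlation is
#' wrong. For balanced Gaussian data the point estimate coincides with the
#' random-intercept GLS estimate; with the correlation fixed at zero it is
#' exactly ordinary least squares.
#'
#' @param summaries Weekly summary data frame ([weekly_summaries()] or
#'   [simulate_weekly_cohort()]).
#' @param profiles Patient profile data frame.
#' @param spec A [model_spec()].
#' @param tol Convergence tolerance on the coefficient update.
#' @param max_iter Maximum number of estimating-equation iterations; if
#'   exceeded the fit is returned with `converged = FALSE` and a warning.
#' @param rho_fix Optional fixed value for the working correlation (e.g. 0
#'   for the independence estimator); `NULL` estimates it.
#' @return A `gee_fit`: coefficients `beta`, `robust_se`, Wald `ci95`
#'   (beta +/- 1.96 se), two-sided normal `p_values`, `rho_hat`, dispersion
#'   `phi`, `n_patients`, `n_weeks_total`, `converged`, `n_iter`.
#' @examples
#' wk <- simulate_weekly_cohort(cohort_config(n_patients = 20, n_weeks = 6,
#'                                            seed = 11))
#' fit <- fit_gee_exchangeable(wk$summaries, wk$profiles, model_spec())
#' fit$beta["arm_digoxin"]
#' @export
fit_gee_exchangeable <- function(summaries, profiles, spec = model_spec(),
                                 tol = 1e-8, max_iter = 100L, rho_fix = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  d <- build_design(summaries, profiles, spec)
  if (length(unique(d$arm)) < 2 || min(table(d$arm)) < 2) {
    stop("need at least 2 patients per arm", call. = FALSE)
  }
  qx <- qr(d$X)
  if (qx$rank < ncol(d$X)) {
    dropped <- colnames(d$X)[qx$pivot[(qx$rank + 1):ncol(d$X)]]
    stop("singular design matrix; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  eng <- gee_engine(d$y, d$X, d$id, tol = tol, max_iter = max_iter,
                    rho_fix = rho_fix)
  se <- sqrt(diag(eng$vbeta))
  ci <- cbind(lower = eng$beta - 1.96 * se, upper = eng$beta + 1.96 * se)
  rownames(ci) <- names(eng$beta)
  structure(list(
    beta = eng$beta, robust_se = stats::setNames(se, names(eng$beta)),
    ci95 = ci,
    p_values = stats::setNames(2 * stats::pnorm(-abs(eng$beta / se)),
                               names(eng$beta)),
    rho_hat = eng$rho, phi = eng$phi,
    n_patients = nlevels(droplevels(d$id)), n_weeks_total = length(d$y),
    converged = eng$converged, n_iter = eng$n_iter, spec = spec
  ), class = "gee_fit")
}

# Estimating-equation iterations with the closed-form exchangeable inverse:
# V_i^{-1} = (phi (1 - rho))^{-1} [I - rho / (1 + (n_i - 1) rho) J].
gee_engine <- function(y, X, id, tol, max_iter, rho_fix = NULL) {
  id <- droplevels(factor(id))
  N <- length(y)
  p <- ncol(X)
  n_i <- as.numeric(rowsum(rep(1, N), id))
  XtX <- crossprod(X)
  beta <- qr.solve(X, y)
  rho <- 0
  phi <- 1
  converged <- FALSE
  it <- 0L
  denom_pairs <- sum(n_i * (n_i - 1) / 2) - p
  while (it < max_iter) {
    it <- it + 1L
    e <- as.numeric(y - X %*% beta)
    phi <- sum(e^2) / (N - p)
    Se <- as.numeric(rowsum(e, id))
    Se2 <- as.numeric(rowsum(e^2, id))
    if (is.null(rho_fix)) {
      rho <- if (denom_pairs > 0) sum((Se^2 - Se2) / 2) / (denom_pairs * phi) else 0
    } else {
      rho <- rho_fix
    }
    lo <- if (max(n_i) > 1) -1 / (max(n_i) - 1) + 1e-6 else -0.999
    rho <- min(max(rho, lo), 0.999)
    c_i <- rho / (1 + (n_i - 1) * rho)
    Sx <- rowsum(X, id)
    Sy <- as.numeric(rowsum(y, id))
    A <- (XtX - crossprod(Sx, Sx * c_i)) / (phi * (1 - rho))
    bv <- (crossprod(X, y) - crossprod(Sx, Sy * c_i)) / (phi * (1 - rho))
    beta_new <- as.numeric(solve(A, bv))
    names(beta_new) <- colnames(X)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  if (!converged) {
    warning("GEE did not converge in ", max_iter, " iterations")
  }
  # robust (sandwich) covariance at the final estimates
  e <- as.numeric(y - X %*% beta)
  Se <- as.numeric(rowsum(e, id))
  c_i <- rho / (1 + (n_i - 1) * rho)
  Sx <- rowsum(X, id)
  Xe <- rowsum(X * e, id)
  U <- (Xe - Sx * (c_i * Se)) / (phi * (1 - rho))
  A <- (XtX - crossprod(Sx, Sx * c_i)) / (phi * (1 - rho))
  Ainv <- solve(A)
  vbeta <- Ainv %*% crossprod(U) %*% Ainv
  list(beta = beta, vbeta = vbeta, rho = rho, phi = phi,
       converged = converged, n_iter = it)
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("<gee_fit> %d patients, %d patient-weeks, rho_hat = %.3f%s\n",
              x$n_patients, x$n_weeks_total, x$rho_hat,
              if (x$converged) "" else " (NOT converged)"))
  tab <- cbind(beta = x$beta, robust_se = x$robust_se, x$ci95, p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Run the full arm-comparison analysis suite
#'
#' Reproduces the repeated-measures analysis set: an unadjusted fit; a fit
#' adjusted for age, gender, heart-failure diagnosis and log NT-proBNP; an
#' activity-adjusted fit adding the weekly step total; and three post-hoc
#' subgroup fits in which week-level records are filtered by their CDC
#' activity band before fitting (so a patient can contribute weeks to more
#' than one subgroup). Subgroup entries record the number of patient-weeks
#' and distinct patients contributing. Subgroups that cannot support a fit
#' (fewer than 2 patients per arm) are skipped with the reason recorded.
#'
#' @param summaries,profiles As in [fit_gee_exchangeable()].
#' @return Named list of `gee_fit` objects (`unadjusted`, `adjusted`,
#'   `activity_adjusted`, `subgroup_low`, `subgroup_minimum_recommended`,
#'   `subgroup_recommended`); skipped entries hold the reason string.
#' @export
run_analysis_suite <- function(summaries, profiles) {
  adj <- c("age", "gender", "heart_failure", "nt_probnp")
  specs <- list(
    unadjusted = model_spec(),
    adjusted = model_spec(adj),
    activity_adjusted = model_spec(c(adj, "weekly_steps")),
    subgroup_low = model_spec(adj, subgroup = "low"),
    subgroup_minimum_recommended = model_spec(adj,
                                              subgroup = "minimum_recommended"),
    subgroup_recommended = model_spec(adj, subgroup = "recommended")
  )
  lapply(specs, function(sp) {
    tryCatch(fit_gee_exchangeable(summaries, profiles, sp),
             error = function(e) {
               message("fit skipped (",
                       if (is.null(sp$subgroup)) "full" else sp$subgroup,
                       "): ", conditionMessage(e))
               structure(list(skipped = TRUE,
                              reason = conditionMessage(e)),
                         class = "gee_skip")
             })
  })
}

#' Two-arm difference test chosen by normality
#'
#' Applies Welch's two-sided t-test when the samples are taken as normal,
#' otherwise the Kruskal-Wallis rank test (equivalent to a two-sample
#' Wilcoxon up to the chi-square formulation).
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param normal Logical: use the t-test (`TRUE`) or Kruskal-Wallis.
#' @return List with `statistic`, `p_value`, `method`.
#' @examples
#' group_difference_test(c(1, 2, 3), c(4, 5, 6), normal = FALSE)$statistic
#' @export
group_difference_test <- function(x, y, normal) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  if (stats::sd(c(x, y)) == 0) {
    stop("degenerate samples: zero variance", call. = FALSE)
  }
  if (isTRUE(normal)) {
    ht <- stats::t.test(x, y)
  } else {
    ht <- stats::kruskal.test(list(x, y))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}

#' Sample size for a repeated-measures two-arm comparison
#'
#' Standard two-sample calculation on patient-level means of `n_weeks`
#' equi-correlated weekly measurements: the variance of a patient mean is
#' \eqn{\sigma^2 (1 + (m - 1)\rho) / m} (the design effect divided by
#' \eqn{m}), and the per-arm size is
#' \eqn{n = \lceil 2 (z_{1-\alpha/2} + z_{power})^2 \mathrm{Var}(\bar y) /
#' \delta^2 \rceil}. Use [power_simulate_repeated()] to verify the attained
#' power of a candidate `n` by simulation.
#'
#' @param delta_bpm True arm difference to detect, bpm (nonzero).
#' @param sd_bpm Standard deviation of a single weekly measurement, bpm.
#' @param rho Exchangeable correlation of the weekly measurements, `[0, 1)`.
#' @param n_weeks Number of weekly measurements per patient.
#' @param alpha Two-sided type-I error rate.
#' @param power Target power in `(0, 1)`.
#' @return List with `n_per_arm`, `var_patient_mean`, `design_effect`.
#' @examples
#' power_repeated_measures(2, 6, 0.91, 20)$n_per_arm
#' @export
power_repeated_measures <- function(delta_bpm, sd_bpm, rho, n_weeks,
                                    alpha = 0.05, power = 0.9) {
  if (delta_bpm == 0) stop("delta_bpm must be nonzero", call. = FALSE)
  stopifnot(sd_bpm > 0, rho >= 0, rho < 1, power > 0, power < 1, n_weeks >= 1)
  de <- 1 + (n_weeks - 1) * rho
  var_mean <- sd_bpm^2 * de / n_weeks
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- ceiling(2 * z^2 * var_mean / delta_bpm^2)
  list(n_per_arm = as.integer(n), var_patient_mean = var_mean,
       design_effect = de)
}

#' Simulated power of the repeated-measures comparison
#'
#' Draws patient-level means from the equi-correlated model underlying
#' [power_repeated_measures()] and applies Welch's t-test, returning the
#' rejection rate.
#'
#' @param n_per_arm Patients per arm.
#' @param delta_bpm,sd_bpm,rho,n_weeks,alpha As in
#'   [power_repeated_measures()].
#' @param n_sim Number of simulated trials.
#' @param seed Integer seed.
#' @return Estimated power (rejection proportion).
#' @export
power_simulate_repeated <- function(n_per_arm, delta_bpm, sd_bpm, rho,
                                    n_weeks, alpha = 0.05, n_sim = 2000L,
                                    seed = 1L) {
  set.seed(as.integer(seed))
  sd_mean <- sd_bpm * sqrt((1 + (n_weeks - 1) * rho) / n_weeks)
  rej <- vapply(seq_len(n_sim), function(i) {
    a <- stats::rnorm(n_per_arm, 0, sd_mean)
    b <- stats::rnorm(n_per_arm, delta_bpm, sd_mean)
    stats::t.test(a, b)$p.value < alpha
  }, TRUE)
  mean(rej)
}
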