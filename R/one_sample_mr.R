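#' Construct an MR fit object
#'
#' Container for a causal (or observational) estimate on the log-odds-per-SD
#' scale with its Wald or bootstrap confidence interval on the OR scale.
#'
#' @param log_or_per_sd point estimate, log-odds per exposure SD
#' @param se standard error of the log-OR
#' @param ci_low,ci_high confidence bounds on the OR scale
#' @param p p-value
#' @param method method label
#' @param n_cases,n_controls sample composition
#' @param diagnostics free-form list (stage-1 R^2/F, bootstrap reps, warnings)
#' @return object of class `mr_fit`
#' @export
mr_fit <- function(log_or_per_sd, se, ci_low, ci_high, p, method,
                   n_cases = NA_integer_, n_controls = NA_integer_,
                   diagnostics = list()) {
  or <- exp(log_or_per_sd)
  if (!is.na(ci_low) && !is.na(ci_high) &&
      !(ci_low <= or + 1e-12 && or <= ci_high + 1e-12))
    stop("CI does not bracket the estimate")
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(log_or_per_sd = log_or_per_sd, se = se, ci_low = ci_low,
                 ci_high = ci_high, p = p, method = method,
                 n_cases = n_cases, n_controls = n_controls,
                 diagnostics = diagnostics),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("<mr_fit:%s> OR %.3f [%.3f-%.3f] per SD, p = %s\n",
              x$method, exp(x$log_or_per_sd), x$ci_low, x$ci_high,
              fmt_p(x$p)))
  if (length(x$diagnostics))
    cat("  diagnostics:", paste(names(x$diagnostics),
                                vapply(x$diagnostics, function(v)
                                  paste(format(v, digits = 4), collapse = ","),
                                  character(1)),
                                sep = "=", collapse = "; "), "\n")
  invisible(x)
}

wald_fit <- function(est, se, method, n_cases, n_controls,
                     diagnostics = list()) {
  z <- qnorm(0.975)
  mr_fit(est, se, exp(est - z * se), exp(est + z * se),
         2 * pnorm(abs(est / se), lower.tail = FALSE), method,
         n_cases, n_controls, diagnostics)
}

check_outcome <- function(case_status) {
  y <- as.integer(case_status)
  if (!all(y %in% c(0L, 1L))) stop("case_status must be 0/1")
  if (sum(y) == 0) stop("zero cases in sample: cannot fit outcome model")
  if (sum(y) == length(y)) stop("zero controls in sample")
  y
}

#' Observational exposure-outcome association
#'
#' Logistic regression of incident case status on the standardised exposure,
#' adjusted for age at baseline. The estimate is an OR per SD of the
#' exposure; attach the raw-scale SD to phrase it per raw unit.
#'
#' @param exposure_z standardised exposure
#' @param case_status 0/1 outcome (incident-only sample)
#' @param age age at baseline
#' @return an [mr_fit()] with method "observational"
#' @export
observational_association <- function(exposure_z, case_status, age) {
  y <- check_outcome(case_status)
  ok <- complete.cases(exposure_z, y, age)
  X <- cbind(intercept = 1, exposure = exposure_z[ok], age = age[ok])
  fit <- fast_logit(X, y[ok])
  if (!fit$converged) stop("observational fit failed (separation?)")
  wald_fit(fit$coef[["exposure"]], fit$se[["exposure"]], "observational",
           sum(y[ok]), sum(ok) - sum(y[ok]))
}

#' Two-stage one-sample MR
#'
#' Stage 1: linear regression of the exposure on the genetic risk score.
#' Stage 2: logistic regression of case status on the stage-1 fitted values,
#' adjusted for age at baseline. The stage-2 coefficient on the fitted values
#' is the causal log-OR per unit of the (supplied, typically standardised)
#' exposure. A stage-1 F below 10 tags a weak-instrument warning in the
#' diagnostics but does not error.
#'
#' @param exposure exposure values (standardise first for per-SD estimates)
#' @param grs genetic risk score
#' @param case_status 0/1 outcome
#' @param age age at baseline
#' @return an [mr_fit()] with method "two-stage", stage-1 R^2/F in
#'   diagnostics
#' @export
two_stage_mr <- function(exposure, grs, case_status, age) {
  y <- check_outcome(case_status)
  ok <- complete.cases(exposure, grs, y, age)
  x <- exposure[ok]; g <- grs[ok]; yy <- y[ok]; a <- age[ok]
  strength <- instrument_strength(g, x)
  s1 <- lm(x ~ g)
  fitted1 <- stats::fitted(s1)
  X <- cbind(intercept = 1, fitted = fitted1, age = a)
  fit <- fast_logit(X, yy)
  if (!fit$converged) stop("stage-2 logistic fit failed")
  diag <- list(stage1_r2 = strength$r_squared,
               stage1_f = strength$f_statistic)
  if (strength$f_statistic < 10) {
    warning("weak instrument: stage-1 F < 10")
    diag$weak_instrument <- TRUE
  }
  wald_fit(fit$coef[["fitted"]], fit$se[["fitted"]], "two-stage",
           sum(yy), length(yy) - sum(yy), diag)
}

#' Percentile bootstrap CI for the two-stage estimator
#'
#' Resamples participants with replacement, refits both stages per replicate
#' and takes the 2.5/97.5 percentiles of the stage-2 coefficient, reported on
#' the OR scale. Deterministic given the seed. Errors if more than 5% of
#' replicates fail to converge.
#'
#' @param exposure,grs,case_status,age as in [two_stage_mr()]
#' @param reps bootstrap repetitions (default 10000, as in large-cohort
#'   practice; scale down in experiments)
#' @param seed RNG seed
#' @param level confidence level (default 0.95)
#' @return list with `ci_low`, `ci_high` (OR scale), `log_or_ci`, `reps`,
#'   `n_failed`
#' @export
bootstrap_ci <- function(exposure, grs, case_status, age, reps = 10000,
                         seed = 1L, level = 0.95) {
  if (reps < 100) stop("reps must be >= 100")
  y <- check_outcome(case_status)
  ok <- complete.cases(exposure, grs, y, age)
  est <- with_seed(seed,
    cpp_boot_two_stage(exposure[ok], grs[ok], y[ok], age[ok], as.integer(reps)))
  failed <- !is.finite(est)
  if (mean(failed) > 0.05)
    stop(sprintf("bootstrap: %.1f%% of replicates failed to converge",
                 100 * mean(failed)))
  alpha <- (1 - level) / 2
  qs <- quantile(est[!failed], c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(ci_low = exp(qs[1]), ci_high = exp(qs[2]), log_or_ci = qs,
       reps = reps, n_failed = sum(failed))
}

#' Exclusion-restriction test
#'
#' Logistic regression of case status on the GRS, adjusted for the exposure
#' and age. Under a valid instrument the GRS carries no information about the
#' outcome once the exposure is held fixed; a small p flags a violation
#' (direct genetic effects / pleiotropy).
#'
#' @param case_status 0/1 outcome
#' @param grs genetic risk score
#' @param exposure exposure values
#' @param age age at baseline
#' @return list `coef`, `se`, `p`, `n`
#' @export
exclusion_restriction_test <- function(case_status, grs, exposure, age) {
  y <- check_outcome(case_status)
  ok <- complete.cases(y, grs, exposure, age)
  g <- grs[ok]
  if (var(g) == 0) stop("GRS is constant")
  X <- cbind(intercept = 1, grs = g, exposure = exposure[ok], age = age[ok])
  if (qr(X)$rank < ncol(X)) stop("collinear design: GRS/exposure degenerate")
  fit <- fast_logit(X, y[ok])
  if (!fit$converged) stop("exclusion-restriction fit failed")
  cf <- fit$coef[["grs"]]; se <- fit$se[["grs"]]
  list(coef = cf, se = se,
       p = 2 * pnorm(abs(cf / se), lower.tail = FALSE), n = sum(ok))
}

#' Stratified two-stage MR
#'
#' Runs [two_stage_mr()] within each stratum; participants with an unknown
#' stratum are dropped from the stratified runs. Strata with zero cases are
#' skipped with a warning.
#'
#' @param exposure,grs,case_status,age as in [two_stage_mr()]
#' @param strata character vector of stratum labels ("unknown" dropped)
#' @return named list of `mr_fit` objects, one per non-empty stratum
#' @export
stratified_mr <- function(exposure, grs, case_status, age, strata) {
  keep <- !is.na(strata) & strata != "unknown"
  labs <- sort(unique(strata[keep]))
  if (length(labs) < 2) stop("need >= 2 non-empty strata")
  fits <- list()
  for (s in labs) {
    i <- keep & strata == s
    f <- tryCatch(two_stage_mr(exposure[i], grs[i], case_status[i], age[i]),
                  error = function(e) {
                    warning(sprintf("stratum '%s' skipped: %s", s,
                                    conditionMessage(e)))
                    NULL
                  })
    if (!is.null(f)) fits[[s]] <- f
  }
  fits
}

#' Fixed-effect heterogeneity test across stratum estimates
#'
#' Cochran's Q against the inverse-variance-weighted pooled estimate, with
#' `I^2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param estimates log-OR estimates per stratum
#' @param ses their standard errors (positive)
#' @return list of class `heterogeneity_result`: `Q`, `df`, `p`, `i_squared`,
#'   `pooled`
#' @export
heterogeneity_test <- function(estimates, ses) {
  k <- length(estimates)
  if (k < 2) stop("need >= 2 estimates")
  if (any(!is.finite(ses)) || any(ses <= 0)) stop("SEs must be positive")
  w <- 1 / ses^2
  pooled <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - pooled)^2)
  df <- as.integer(k - 1)
  structure(list(Q = Q, df = df,
                 p = pchisq(Q, df, lower.tail = FALSE),
                 i_squared = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0,
                 pooled = pooled),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Heterogeneity: Q = %.3f (df = %d), p = %s, I^2 = %.1f%%\n",
              x$Q, x$df, fmt_p(x$p), x$i_squared))
  invisible(x)
}
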