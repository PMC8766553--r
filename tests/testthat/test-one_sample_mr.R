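test_that("observational association flags confounded nulls that MR clears", {
  # theta = 0 but strong confounding: observational OR departs from 1 while
  # the two-stage estimate stays near 0 (oracle = adjusted fit with true U)
  coh <- tiny_cohort(seed = 14, theta = 0, n = 50000, r2 = 0.05,
                     prevalence = 0.05)
  v <- cohort_analysis_vars(coh)
  obs <- observational_association(v$z, v$y, v$age)
  expect_gt(obs$log_or_per_sd / obs$se, 3)  # biased upwards (conf +/+)
  ts <- two_stage_mr(v$z, v$grs, v$y, v$age)
  expect_lt(abs(ts$log_or_per_sd / ts$se), 3)
  # oracle: adjusting for the true confounder removes the observational bias
  u <- coh$phenotypes$.oracle_confounder
  adj <- summary(glm(v$y ~ v$z + u + v$age, family = binomial()))$coefficients
  expect_lt(abs(adj[2, 1]), 3 * adj[2, 2])

  # per-SD OR phrased per raw unit by attaching the SD
  sd_raw <- attr(standardise(coh$phenotypes$exposure_raw), "scale")
  expect_equal(sd_raw, 5.14, tolerance = 0.02)
  expect_equal(round(exp(-0.357), 2), 0.70)
})

test_that("two-stage MR recovers theta in the rare-outcome regime", {
  coh <- tiny_cohort(seed = 15, theta = -0.3, n = 100000, r2 = 0.02,
                     prevalence = 0.02)
  v <- cohort_analysis_vars(coh)
  ts <- two_stage_mr(v$z, v$grs, v$y, v$age)
  expect_lt(abs(ts$log_or_per_sd - (-0.3)), 3 * ts$se)
  expect_gt(ts$diagnostics$stage1_f, 10)
  ci <- bootstrap_ci(v$z, v$grs, v$y, v$age, reps = 500, seed = 77)
  expect_true(ci$ci_low < exp(-0.3) && exp(-0.3) < ci$ci_high)
})

test_that("a weak instrument warns but still returns a fit", {
  coh <- tiny_cohort(seed = 16, theta = 0, n = 2000, r2 = 0.001,
                     prevalence = 0.1)
  v <- cohort_analysis_vars(coh)
  expect_warning(f <- two_stage_mr(v$z, v$grs, v$y, v$age),
                 "weak instrument")
  expect_true(isTRUE(f$diagnostics$weak_instrument))
})

test_that("two-stage equals the Wald ratio in the linear limit", {
  # identity-link oracle: stage-2 linear coefficient on fitted values equals
  # cov(Y, G)/cov(X, G)
  set.seed(4)
  n <- 400
  g <- rnorm(n); x <- 0.5 * g + rnorm(n); y <- 0.7 * x + rnorm(n)
  fitted1 <- fitted(lm(x ~ g))
  b2 <- coef(lm(y ~ fitted1))[2]
  expect_equal(unname(b2), cov(y, g) / cov(x, g), tolerance = 1e-8)
})

test_that("bootstrap CIs are deterministic and stabilise with reps", {
  coh <- tiny_cohort(seed = 17, theta = -0.3, n = 20000, r2 = 0.05,
                     prevalence = 0.05)
  v <- cohort_analysis_vars(coh)
  c1 <- bootstrap_ci(v$z, v$grs, v$y, v$age, reps = 500, seed = 5)
  c2 <- bootstrap_ci(v$z, v$grs, v$y, v$age, reps = 500, seed = 5)
  expect_identical(c1, c2)
  c3 <- bootstrap_ci(v$z, v$grs, v$y, v$age, reps = 5000, seed = 5)
  width <- diff(c3$log_or_ci)
  expect_lt(abs(c1$log_or_ci[1] - c3$log_or_ci[1]), 0.1 * width)
  expect_lt(abs(c1$log_or_ci[2] - c3$log_or_ci[2]), 0.1 * width)
  expect_error(bootstrap_ci(v$z, v$grs, v$y, v$age, reps = 50), "reps")
})

test_that("exclusion-restriction test behaves under null and pleiotropy", {
  coh <- tiny_cohort(seed = 18, theta = -0.3, n = 20000, r2 = 0.05,
                     prevalence = 0.05)
  v <- cohort_analysis_vars(coh)
  ex <- exclusion_restriction_test(v$y, v$grs, v$z, v$age)
  expect_lt(abs(ex$coef), 4 * ex$se)

  # strong direct SNP -> outcome effects: the test must reject
  cfg <- sim_config_standard(seed = 19, theta = 0, n = 50000, r2 = 0.05,
                             prevalence = 0.05)
  cfg$pleiotropy <- rep(0.1, length(cfg$mafs))
  cohp <- simulate_cohort(cfg)
  vp <- cohort_analysis_vars(cohp)
  exp_ <- exclusion_restriction_test(vp$y, vp$grs, vp$z, vp$age)
  expect_lt(exp_$p, 0.001)

  expect_error(exclusion_restriction_test(v$y, rep(1, length(v$y)), v$z,
                                          v$age), "constant")
})

test_that("stratified MR detects true effect modification", {
  cfg <- sim_config_standard(seed = 20, theta = -0.2, n = 60000, r2 = 0.1,
                             prevalence = 0.1,
                             stratum_spec = c(high = 3, low = 1))
  coh <- simulate_cohort(cfg)
  v <- cohort_analysis_vars(coh)
  fits <- stratified_mr(v$z, v$grs, v$y, v$age, coh$phenotypes$stratum)
  expect_named(fits, c("high", "low"))
  het <- heterogeneity_test(vapply(fits, `[[`, 0, "log_or_per_sd"),
                            vapply(fits, `[[`, 0, "se"))
  expect_lt(het$p, 0.05)

  # homogeneous truth: Q is usually small; check p is not extreme
  cfg0 <- sim_config_standard(seed = 21, theta = -0.2, n = 60000, r2 = 0.1,
                              prevalence = 0.1,
                              stratum_spec = c(a = 1, b = 1))
  coh0 <- simulate_cohort(cfg0)
  v0 <- cohort_analysis_vars(coh0)
  fits0 <- stratified_mr(v0$z, v0$grs, v0$y, v0$age, coh0$phenotypes$stratum)
  het0 <- heterogeneity_test(vapply(fits0, `[[`, 0, "log_or_per_sd"),
                             vapply(fits0, `[[`, 0, "se"))
  expect_gt(het0$p, 0.001)

  expect_error(stratified_mr(v$z, v$grs, v$y, v$age,
                             rep("only", length(v$z))), "2 non-empty strata")
})

test_that("heterogeneity arithmetic matches hand computation", {
  h <- heterogeneity_test(c(0.2, 0.2), c(0.1, 0.1))
  expect_equal(h$Q, 0)
  expect_equal(h$i_squared, 0)
  expect_equal(h$p, 1)

  # weights 100 each, pooled 0.4, Q = 100*0.04 + 100*0.04 = 8
  h2 <- heterogeneity_test(c(0.2, 0.6), c(0.1, 0.1))
  expect_equal(h2$Q, 8.0)
  expect_equal(h2$df, 1)
  expect_equal(h2$i_squared, 87.5)

  # brute-force Q for k = 3 with an outlier
  est <- c(0.1, 0.15, 0.9); se <- rep(0.2, 3)
  w <- 1 / se^2
  pooled <- sum(w * est) / sum(w)
  q_brute <- sum(w * (est - pooled)^2)
  h3 <- heterogeneity_test(est, se)
  expect_equal(h3$Q, q_brute, tolerance = 1e-12)

  # invariance to adding a constant
  h4 <- heterogeneity_test(est + 5, se)
  expect_equal(h4$Q, h3$Q, tolerance = 1e-10)

  expect_error(heterogeneity_test(c(0.1, 0.2), c(0.1, 0)), "positive")
  expect_error(heterogeneity_test(0.1, 0.1), ">= 2")
})

test_that("mr_fit enforces its invariants", {
  expect_error(mr_fit(0.5, 0.1, ci_low = 2, ci_high = 3, p = 0.5, "m"),
               "bracket")
  f <- mr_fit(log(2), 0.1, 1.8, 2.3, p = 0, method = "m")
  expect_gt(f$p, 0)
})
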