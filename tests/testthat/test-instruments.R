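# a 4-participant cohort with hand-set dosages and alleles
mini_cohort <- function() {
  dos <- matrix(c(2, 1, 0, 2,
                  0, 1, 2, 1,
                  1, 1, 0, 2), nrow = 4,
                dimnames = list(paste0("p", 1:4), c("rs1", "rs2", "rs3")))
  meta <- data.frame(id = c("rs1", "rs2", "rs3"),
                     effect_allele = c("A", "G", "A"),
                     other_allele = c("G", "T", "T"),
                     eaf = c(0.3, 0.4, 0.49), stringsAsFactors = FALSE)
  list(dosages = dos, variant_meta = meta)
}

test_that("allele alignment covers identity, swap, complement and palindromes", {
  coh <- mini_cohort()
  # rs1: same alleles; rs2: swapped; rs3 palindromic A/T at eaf 0.49 -> drop
  iset <- instrument_set(c("rs1", "rs2", "rs3"),
                         effect_allele = c("A", "T", "A"),
                         other_allele = c("G", "G", "T"),
                         weight = c(0.1, 0.2, 0.3),
                         eaf = c(0.3, 0.6, 0.49))
  expect_warning(al <- align_dosages(coh, iset), "palindromic")
  expect_equal(colnames(al), c("rs1", "rs2"))
  expect_equal(unname(al[, "rs1"]), coh$dosages[, "rs1"], ignore_attr = TRUE)
  expect_equal(unname(al[, "rs2"]), 2 - coh$dosages[, "rs2"],
               ignore_attr = TRUE)
  expect_equal(attr(al, "dropped")$reason, "palindromic, frequency-unresolvable")

  # strand complement: instrument reports T/C for cohort A/G (rs1)
  iset2 <- instrument_set("rs1", "T", "C", weight = 0.1, eaf = 0.3)
  al2 <- align_dosages(coh, iset2)
  expect_equal(unname(al2[, "rs1"]), unname(coh$dosages[, "rs1"]))
  # complement + swap: C/T for cohort A/G
  iset3 <- instrument_set("rs1", "C", "T", weight = 0.1, eaf = 0.7)
  al3 <- align_dosages(coh, iset3)
  expect_equal(unname(al3[, "rs1"]), 2 - unname(coh$dosages[, "rs1"]))
})

test_that("frequency-resolvable palindromic variants align by frequency class", {
  dos <- matrix(c(2, 2, 1, 2, 1, 2), ncol = 1,
                dimnames = list(NULL, "rs9"))  # freq 10/12 = 0.83
  coh <- list(dosages = dos,
              variant_meta = data.frame(id = "rs9", effect_allele = "A",
                                        other_allele = "T", eaf = 0.83,
                                        stringsAsFactors = FALSE))
  keep <- align_dosages(coh, instrument_set("rs9", "A", "T", 1, eaf = 0.8))
  expect_equal(unname(keep[, 1]), dos[, 1], ignore_attr = TRUE)
  flip <- align_dosages(coh, instrument_set("rs9", "A", "T", 1, eaf = 0.2))
  expect_equal(unname(flip[, 1]), 2 - dos[, 1], ignore_attr = TRUE)
})

test_that("unalignable majorities are a hard error", {
  coh <- mini_cohort()
  iset <- instrument_set(c("rsX", "rsY", "rs1"),
                         effect_allele = c("A", "A", "A"),
                         other_allele = c("G", "G", "G"),
                         weight = c(1, 1, 1), eaf = 0.3)
  expect_error(suppressWarnings(align_dosages(coh, iset)), "50%")
})

test_that("GRS is the weighted dosage sum, with mean imputation for missings", {
  m <- matrix(c(2, 1, 0, 1, 1, 1), nrow = 2, byrow = TRUE)
  expect_equal(compute_grs(m, weights = c(0.1, -0.2, 0.3)), c(0.0, 0.2))
  expect_equal(compute_grs(m, weights = c(0, 0, 0)), c(0, 0))
  expect_equal(compute_grs(matrix(2), weights = 0.5), 1.0)

  mm <- matrix(c(2, NA, 0, 2), nrow = 2)
  # column 1 = (2, NA), column 2 = (0, 2); the NA is replaced by
  # 2*eaf = 2*0.25 = 0.5 when eaf is known
  expect_equal(compute_grs(mm, weights = c(1, 1), eaf = c(0.25, 0.5)),
               c(2 + 0, 0.5 + 2))
  # without eaf, the observed column mean (2) fills in
  expect_equal(compute_grs(mm, weights = c(1, 1)), c(2 + 0, 2 + 2))
})

test_that("allele-flip equivariance and GRS linearity hold", {
  coh <- tiny_cohort(seed = 5, n = 500, n_snps = 8)
  meta <- coh$variant_meta
  w <- coh$config$snp_effects
  iset <- instrument_set(meta$id, meta$effect_allele, meta$other_allele,
                         weight = w, eaf = meta$eaf)
  g1 <- compute_grs(align_dosages(coh, iset))
  flipped <- instrument_set(meta$id, meta$other_allele, meta$effect_allele,
                            weight = -w, eaf = 1 - meta$eaf)
  g2 <- compute_grs(align_dosages(coh, flipped))
  # flipping alleles and negating weights shifts the score by -2*sum(w)
  expect_equal(g2, g1 - 2 * sum(w), tolerance = 1e-10)

  al <- align_dosages(coh, iset)
  w2 <- rev(w)
  expect_equal(compute_grs(al, weights = w + w2),
               compute_grs(al, weights = w) + compute_grs(al, weights = w2),
               tolerance = 1e-12)
})

test_that("instrument strength matches the closed-form F identity", {
  coh <- tiny_cohort(seed = 8, n = 2000, r2 = 0.1)
  v <- cohort_analysis_vars(coh)
  s <- instrument_strength(v$grs, v$z)
  expect_equal(s$f_statistic, (s$n - 2) * s$r_squared / (1 - s$r_squared),
               tolerance = 1e-8)
  # closed form: R^2 = 0.5 at n = 102 gives F = 100
  expect_equal((102 - 2) * 0.5 / (1 - 0.5), 100)

  expect_error(instrument_strength(rep(1, 100), rnorm(100)), "zero-variance")
  x <- rnorm(100)
  expect_error(instrument_strength(x, x), "undefined")

  # independent exposure: null R^2 is tiny with high probability
  set.seed(1)
  s0 <- instrument_strength(rnorm(10000), rnorm(10000))
  expect_lt(s0$r_squared, 0.001)
})

test_that("in-sample weight estimation recovers generative effects", {
  cfg <- sim_config(20000, mafs = rep(0.3, 3),
                    snp_effects = c(0.15, 0.05, 0), baseline_logit = -3,
                    noise_sd = 1, seed = 31)
  coh <- simulate_cohort(cfg)
  iset <- estimate_weights_in_sample(
    coh, exclude_mask = coh$phenotypes$outcome == 1, sex = "F",
    exposure_col = "exposure_raw")
  # exposure_raw = 27 + 5.14 * X, so weights are on the 5.14-scaled scale
  w <- iset$weight / 5.14
  n_eff <- sum(coh$phenotypes$outcome == 0)
  se <- 1 / sqrt(n_eff * 2 * 0.3 * 0.7)  # approx slope SE, sd(resid) ~ 1
  expect_lt(abs(w[1] - 0.15), 4 * se)
  expect_lt(abs(w[2] - 0.05), 4 * se)
  expect_lt(abs(w[3] - 0.00), 4 * se)

  # permuted exposure: weights are null
  coh2 <- coh
  set.seed(99)
  coh2$phenotypes$exposure_raw <- sample(coh$phenotypes$exposure_raw)
  iset2 <- estimate_weights_in_sample(
    coh2, exclude_mask = rep(FALSE, 20000), sex = "F")
  expect_true(all(abs(iset2$weight / 5.14) < 4 * se))

  expect_error(estimate_weights_in_sample(
    coh, exclude_mask = rep(TRUE, 20000), sex = "F"), "all participants")
})

test_that("adding a truly associated variant does not reduce R^2", {
  coh <- tiny_cohort(seed = 12, n = 20000, n_snps = 10, r2 = 0.05)
  v <- cohort_analysis_vars(coh)
  w <- coh$config$snp_effects
  g_partial <- drop(coh$dosages[, 1:9] %*% w[1:9])
  s_partial <- instrument_strength(g_partial, v$z)
  s_full <- instrument_strength(v$grs, v$z)
  expect_gt(s_full$r_squared, s_partial$r_squared)
})
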