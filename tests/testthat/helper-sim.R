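# Shared fixtures, built in code at test time.

# A small cohort with known structure, cached per (seed, ...) within a run.
tiny_cohort <- function(seed = 1, theta = 0, n = 5000, r2 = 0.05,
                        prevalence = 0.05, ...) {
  simulate_cohort(sim_config_standard(seed = seed, theta = theta, n = n,
                                      r2 = r2, prevalence = prevalence, ...))
}

# Standardised exposure + GRS from the true generative weights.
cohort_analysis_vars <- function(coh) {
  list(z = as.numeric(standardise(coh$phenotypes$exposure_raw)),
       grs = drop(coh$dosages %*% coh$config$snp_effects),
       y = coh$phenotypes$outcome,
       age = coh$phenotypes$age)
}

# Independent weighted-least-squares oracle via explicit normal-equation
# sums (no matrix solve shared with the implementation path).
wls_oracle <- function(X, y, w) {
  p <- ncol(X)
  A <- matrix(0, p, p)
  b <- numeric(p)
  for (i in seq_len(nrow(X))) {
    xi <- X[i, ]
    A <- A + w[i] * tcrossprod(xi)
    b <- b + w[i] * y[i] * xi
  }
  solve(A, b)
}
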