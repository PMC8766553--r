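#' Simulation configuration for synthetic MR cohorts
#'
#' Describes a complete generative world: independent biallelic SNPs under
#' Hardy-Weinberg equilibrium, a continuous exposure that is a linear function
#' of allele dosages plus an unobserved standard-normal confounder plus
#' Gaussian noise, and a binary outcome from a logistic model with a causal
#' exposure effect, a confounder effect, optional direct (pleiotropic) SNP
#' effects, an optional quadratic exposure term, and optional stratum-specific
#' multipliers on the causal effect.
#'
#' @param n_individuals number of participants
#' @param mafs effect-allele frequencies, all strictly inside (0, 1)
#' @param snp_effects per-allele effect of each SNP on the exposure
#'   (exposure units per effect-allele copy)
#' @param theta causal effect of the exposure on the outcome, log-odds per
#'   exposure unit
#' @param confounder_effect_x confounder-to-exposure slope
#' @param confounder_effect_y confounder-to-outcome log-odds slope
#' @param pleiotropy per-SNP direct log-odds effect on the outcome
#'   (default all zero)
#' @param baseline_logit intercept of the outcome model; controls prevalence
#' @param stratum_spec optional named numeric vector of multipliers on
#'   `theta`; participants are assigned uniformly to the named strata
#' @param prevalent_fraction fraction of cases whose diagnosis predates
#'   baseline
#' @param noise_sd SD of the exposure residual
#' @param theta_quadratic log-odds coefficient on the squared exposure
#'   (0 = linear causal effect)
#' @param insitu_fraction fraction of non-cases given an in-situ-only
#'   diagnosis record, to exercise exclusion rules
#' @param sex cohort sex label ("F" or "M")
#' @param seed master seed; per-operation substreams are derived from it
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_individuals, mafs, snp_effects, theta = 0,
                       confounder_effect_x = 0, confounder_effect_y = 0,
                       pleiotropy = NULL, baseline_logit = -3.95,
                       stratum_spec = NULL, prevalent_fraction = 0.1,
                       noise_sd = 1, theta_quadratic = 0,
                       insitu_fraction = 0.002, sex = "F", seed = 1L) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (any(!is.finite(mafs)) || any(mafs <= 0) || any(mafs >= 1))
    stop("maf out of range (0,1)")
  if (length(snp_effects) != length(mafs))
    stop("lengths of mafs and snp_effects must agree")
  if (is.null(pleiotropy)) pleiotropy <- rep(0, length(mafs))
  if (length(pleiotropy) != length(mafs))
    stop("lengths of mafs and pleiotropy must agree")
  if (prevalent_fraction < 0 || prevalent_fraction > 1)
    stop("prevalent_fraction must be in [0,1]")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!is.null(stratum_spec) &&
      (is.null(names(stratum_spec)) || any(names(stratum_spec) == "")))
    stop("stratum_spec must be a named numeric vector")
  structure(list(
    n_individuals = as.integer(n_individuals), mafs = as.numeric(mafs),
    snp_effects = as.numeric(snp_effects), theta = theta,
    confounder_effect_x = confounder_effect_x,
    confounder_effect_y = confounder_effect_y,
    pleiotropy = as.numeric(pleiotropy), baseline_logit = baseline_logit,
    stratum_spec = stratum_spec, prevalent_fraction = prevalent_fraction,
    noise_sd = noise_sd, theta_quadratic = theta_quadratic,
    insitu_fraction = insitu_fraction, sex = sex, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Standard recovery-test configuration
#'
#' The reference world used throughout the validation suite: 30 independent
#' SNPs with evenly spaced MAFs in (0.05, 0.45) whose per-allele effects are
#' sized so the instrument explains `r2` of the exposure variance, a unit-
#' variance exposure (residual SD chosen to complete the variance budget),
#' confounder slopes of 0.5 on both exposure and outcome, and ~2% outcome
#' prevalence so the conditional odds ratio approximates the causal effect.
#'
#' @param seed master seed
#' @param theta causal log-odds per exposure SD
#' @param n cohort size
#' @param n_snps number of instruments
#' @param r2 exposure variance explained by the instruments
#' @param conf_x,conf_y confounder slopes on exposure / outcome
#' @param prevalence approximate outcome prevalence
#' @param ... passed on to [sim_config()]
#' @return a `sim_config`
#' @export
sim_config_standard <- function(seed, theta = 0, n = 100000L, n_snps = 30L,
                                r2 = 0.02, conf_x = 0.5, conf_y = 0.5,
                                prevalence = 0.02, ...) {
  mafs <- seq(0.05, 0.45, length.out = n_snps)
  per_snp_var <- r2 / n_snps
  effects <- sqrt(per_snp_var / (2 * mafs * (1 - mafs)))
  resid_var <- 1 - r2 - conf_x^2
  if (resid_var <= 0) stop("r2 + conf_x^2 must be < 1 for unit variance")
  sim_config(n_individuals = n, mafs = mafs, snp_effects = effects,
             theta = theta, confounder_effect_x = conf_x,
             confounder_effect_y = conf_y,
             baseline_logit = stats::qlogis(prevalence),
             noise_sd = sqrt(resid_var), seed = seed, ...)
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Each column j is drawn independently as Binomial(2, maf_j) per individual.
#'
#' @param n number of individuals
#' @param mafs effect-allele frequencies in (0,1)
#' @param seed RNG seed; the caller's RNG state is restored on exit
#' @return an `n` x `length(mafs)` integer dosage matrix
#' @export
simulate_genotypes <- function(n, mafs, seed) {
  if (n < 1) stop("n must be >= 1")
  if (any(!is.finite(mafs)) || any(mafs <= 0) || any(mafs >= 1))
    stop("maf out of range (0,1)")
  with_seed(seed, {
    g <- vapply(mafs, function(p) rbinom(n, 2L, p), numeric(n))
    if (n == 1L) g <- matrix(g, nrow = 1L)
    colnames(g) <- sprintf("rs%d", seq_along(mafs))
    g
  })
}

# deterministic non-palindromic allele pairs for simulated variants
.complement <- c(A = "T", T = "A", C = "G", G = "C")

# vectorised per-SNP simple linear regression of x on each dosage column
snp_linear_stats <- function(g, x) {
  n <- nrow(g)
  gc <- scale(g, center = TRUE, scale = FALSE)
  sxx <- colSums(gc^2)
  beta <- drop(crossprod(gc, x - mean(x))) / sxx
  rss <- sum((x - mean(x))^2) - beta^2 * sxx
  se <- sqrt(rss / (n - 2) / sxx)
  p <- 2 * pt(abs(beta / se), df = n - 2, lower.tail = FALSE)
  list(beta = beta, se = se, p = p)
}

sim_variant_meta <- function(mafs, seed) {
  k <- length(mafs)
  with_seed(seed, {
    ea <- sample(c("A", "T", "C", "G"), k, replace = TRUE)
    oa <- vapply(ea, function(a) {
      sample(setdiff(c("A", "T", "C", "G"), c(a, .complement[[a]])), 1L)
    }, character(1))
  })
  data.frame(id = sprintf("rs%d", seq_len(k)), effect_allele = ea,
             other_allele = unname(oa), eaf = mafs,
             stringsAsFactors = FALSE)
}

#' Simulate an individual-level cohort with known causal structure
#'
#' Generates genotypes, exposure, binary outcome, ICD-style diagnosis records
#' with dates (a `prevalent_fraction` of cases dated before the fixed baseline
#' of 2008-01-01), menopause fields, workplace-chemical questionnaire answers,
#' and optional effect-modification strata. The confounder is retained in the
#' phenotype table as `.oracle_confounder` for validation only; analysis
#' operations never read it.
#'
#' @param config a [sim_config()]
#' @return an object of class `grsmr_cohort`: list with `phenotypes`
#'   (data.frame), `dosages` (matrix), `variant_meta`, `diagnoses`
#'   (long-format id/code/date), `baseline_date`, and `config`
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  k <- length(config$mafs)
  g <- simulate_genotypes(n, config$mafs,
                          substream_seed(config$seed, "genotypes"))
  meta <- sim_variant_meta(config$mafs, substream_seed(config$seed, "alleles"))
  baseline_date <- as.Date("2008-01-01")

  with_seed(substream_seed(config$seed, "phenotypes"), {
    u <- rnorm(n)
    eps <- rnorm(n, 0, config$noise_sd)
    x <- drop(g %*% config$snp_effects) + config$confounder_effect_x * u + eps

    stratum <- rep("all", n)
    mult <- rep(1, n)
    if (!is.null(config$stratum_spec)) {
      stratum <- sample(names(config$stratum_spec), n, replace = TRUE)
      mult <- unname(config$stratum_spec[stratum])
    }
    eta <- config$baseline_logit + config$theta * mult * x +
      config$theta_quadratic * x^2 + config$confounder_effect_y * u +
      drop(g %*% config$pleiotropy)
    y <- rbinom(n, 1L, stats::plogis(eta))

    age <- sample(40:69, n, replace = TRUE)
    id <- sprintf("id%07d", seq_len(n))

    # diagnosis records: invasive code for cases; a sliver of in-situ-only
    # records among non-cases to exercise the exclusion rules
    inv_code <- if (config$sex == "F") "C50" else "C61"
    ins_code <- if (config$sex == "F") "D05" else "D075"
    case_idx <- which(y == 1L)
    n_prev <- round(config$prevalent_fraction * length(case_idx))
    prev_idx <- if (n_prev > 0) case_idx[seq_len(n_prev)] else integer(0)
    offs <- integer(n)
    offs[case_idx] <- sample(30:3650, length(case_idx), replace = TRUE)
    ddate <- rep(as.Date(NA), n)
    ddate[case_idx] <- baseline_date + offs[case_idx]
    ddate[prev_idx] <- baseline_date - offs[prev_idx]
    insitu_idx <- which(y == 0L)
    insitu_idx <- insitu_idx[runif(length(insitu_idx)) < config$insitu_fraction]

    diagnoses <- rbind(
      data.frame(id = id[case_idx], code = rep(inv_code, length(case_idx)),
                 date = ddate[case_idx], stringsAsFactors = FALSE),
      data.frame(id = id[insitu_idx], code = rep(ins_code, length(insitu_idx)),
                 date = rep(baseline_date + 100, length(insitu_idx)),
                 stringsAsFactors = FALSE)
    )
    diagnoses <- diagnoses[order(diagnoses$id), , drop = FALSE]
    rownames(diagnoses) <- NULL

    # menopause fields (female cohorts): reported age at menopause, or NA if
    # not yet occurred / unreported
    meno_age <- round(rnorm(n, 50, 3))
    not_yet <- age < meno_age
    reported <- runif(n) > 0.05
    menopause_age <- ifelse(!not_yet & reported, meno_age, NA_real_)
    meno_baseline <- ifelse(!reported, NA_character_,
                            ifelse(not_yet, "pre", "post"))

    chem_levels <- c("Often", "Sometimes", "Rarely/never")
    chem <- replicate(7, {
      a <- sample(chem_levels, n, replace = TRUE, prob = c(0.05, 0.10, 0.85))
      a[runif(n) < 0.05] <- NA_character_
      a
    }, simplify = FALSE)
    names(chem) <- paste0("chem_", 1:7)

    age_at_diag <- ifelse(y == 1L,
                          age + as.numeric(ddate - baseline_date) / 365.25,
                          NA_real_)

    phen <- data.frame(
      id = id, sex = config$sex, age = age,
      exposure_raw = 27 + 5.14 * x,
      outcome = y, stratum = stratum,
      biomarker = u + rnorm(n, 0, 0.5),
      menopause_age = menopause_age,
      menopause_status_baseline = meno_baseline,
      age_at_diagnosis = age_at_diag,
      .oracle_confounder = u,
      stringsAsFactors = FALSE
    )
    for (nm in names(chem)) phen[[nm]] <- chem[[nm]]
  })

  rownames(g) <- phen$id
  structure(list(phenotypes = phen, dosages = g, variant_meta = meta,
                 diagnoses = diagnoses, baseline_date = baseline_date,
                 config = config),
            class = "grsmr_cohort")
}

#' @export
print.grsmr_cohort <- function(x, ...) {
  cat(sprintf("<grsmr_cohort> %d participants, %d variants, %d cases (%s)\n",
              nrow(x$phenotypes), ncol(x$dosages),
              sum(x$phenotypes$outcome), x$config$sex))
  invisible(x)
}

#' Simulate a two-sample summary-statistics study
#'
#' Draws two independent cohorts from the same generative configuration.
#' Exposure statistics are per-SNP linear regressions of the exposure on
#' dosage in sample A; outcome statistics are per-SNP logistic regressions of
#' the outcome on dosage in sample B. Monomorphic simulated variants are
#' dropped with a warning.
#'
#' @param config a [sim_config()]
#' @param n_exposure,n_outcome sample sizes of the two non-overlapping samples
#' @param seed seed for the pair of samples
#' @return list of class `two_sample_study` with `exposure_stats`,
#'   `outcome_stats` (SNP, effect_allele, other_allele, eaf, beta, se, pval,
#'   n) and `truth` (the config)
#' @export
simulate_summary_stats <- function(config, n_exposure, n_outcome, seed) {
  stopifnot(inherits(config, "sim_config"))
  cfg_a <- config; cfg_a$n_individuals <- as.integer(n_exposure)
  cfg_a$seed <- substream_seed(seed, "expo-sample")
  cfg_b <- config; cfg_b$n_individuals <- as.integer(n_outcome)
  cfg_b$seed <- substream_seed(seed, "outcome-sample")
  coh_a <- simulate_cohort(cfg_a)
  coh_b <- simulate_cohort(cfg_b)

  xa <- standardise(coh_a$phenotypes$exposure_raw)
  ga <- coh_a$dosages
  keep <- apply(ga, 2, function(v) var(v) > 0)
  gb <- coh_b$dosages
  keep <- keep & apply(gb, 2, function(v) var(v) > 0)
  if (!all(keep))
    warning(sprintf("dropped %d monomorphic simulated variant(s)",
                    sum(!keep)))
  ga <- ga[, keep, drop = FALSE]
  gb <- gb[, keep, drop = FALSE]
  meta <- coh_a$variant_meta[keep, , drop = FALSE]

  ls <- snp_linear_stats(ga, xa)
  bx <- ls$beta; se_x <- ls$se; p_x <- ls$p
  na <- nrow(ga)

  yb <- coh_b$phenotypes$outcome
  ofit <- cpp_snp_logit(gb, yb)
  by <- ofit[, 1]; se_y <- ofit[, 2]
  p_y <- 2 * pnorm(abs(by / se_y), lower.tail = FALSE)

  mk <- function(beta, se, p, eaf, n) data.frame(
    SNP = meta$id, effect_allele = meta$effect_allele,
    other_allele = meta$other_allele, eaf = eaf, beta = beta, se = se,
    pval = p, n = n, stringsAsFactors = FALSE)
  structure(list(
    exposure_stats = mk(bx, se_x, p_x, colMeans(ga) / 2, na),
    outcome_stats = mk(by, se_y, p_y, colMeans(gb) / 2, nrow(gb)),
    truth = config
  ), class = "two_sample_study")
}

#' Simulate a summary-level two-sample study parametrically
#'
#' Direct draw at the summary level from the generative identity
#' `E[by] = pleiotropy + theta * bx`, with Gaussian estimation noise at the
#' stated standard errors. Used for large Monte-Carlo calibration experiments
#' (e.g. Egger intercept test size) where individual-level simulation would be
#' needlessly slow; the identity is the same one the individual-level
#' generator induces for a rare outcome.
#'
#' @param k number of variants
#' @param theta causal slope
#' @param bx_range range of true exposure effects (uniform)
#' @param pleiotropy_mean,pleiotropy_sd per-variant direct effects
#'   alpha_j ~ N(mean, sd^2); mean 0 with sd > 0 is balanced pleiotropy,
#'   nonzero mean is directional
#' @param se_x,se_y per-variant standard errors (recycled to length k)
#' @param seed RNG seed
#' @return a `harmonised_study` data.frame (SNP, bx, se_x, by, se_y)
#' @export
simulate_summary_study <- function(k, theta, bx_range = c(0.02, 0.1),
                                   pleiotropy_mean = 0, pleiotropy_sd = 0,
                                   se_x = 0.004, se_y = 0.01, seed = 1L) {
  stopifnot(k >= 3)
  se_x <- rep_len(se_x, k); se_y <- rep_len(se_y, k)
  with_seed(seed, {
    bx_true <- runif(k, bx_range[1], bx_range[2])
    alpha <- rnorm(k, pleiotropy_mean, pleiotropy_sd)
    bx <- bx_true + rnorm(k, 0, se_x)
    by <- alpha + theta * bx_true + rnorm(k, 0, se_y)
  })
  new_harmonised_study(data.frame(
    SNP = sprintf("rs%d", seq_len(k)), bx = bx, se_x = se_x, by = by,
    se_y = se_y, stringsAsFactors = FALSE))
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' Writes `phenotypes.tsv`, `dosages.tsv` (participant ID + one column per
#' variant), `variants.tsv`, `diagnoses.tsv` (long format, ISO-8601 dates)
#' and `truth.json` (the generative configuration). Missing values are empty
#' fields.
#'
#' @param cohort a `grsmr_cohort`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "grsmr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(d, f) data.table::fwrite(d, file.path(dir, f), sep = "\t",
                                          na = "", quote = FALSE)
  fw(cohort$phenotypes, "phenotypes.tsv")
  dos <- data.table::as.data.table(cohort$dosages)
  dos <- cbind(data.table::data.table(id = rownames(cohort$dosages)), dos)
  fw(dos, "dosages.tsv")
  fw(cohort$variant_meta, "variants.tsv")
  fw(cohort$diagnoses, "diagnoses.tsv")
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Write a summary-statistics table to TSV
#' @param stats data.frame with columns SNP, effect_allele, other_allele,
#'   eaf, beta, se, pval, n
#' @param path output file
#' @return `path`, invisibly
#' @export
write_summary_stats <- function(stats, path) {
  data.table::fwrite(stats, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}
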