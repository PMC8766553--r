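new_harmonised_study <- function(df) {
  stopifnot(all(c("SNP", "bx", "se_x", "by", "se_y") %in% names(df)))
  if (any(!is.finite(df$bx)) || any(!is.finite(df$by)))
    stop("missing bx/by not allowed in a harmonised study")
  if (any(!is.finite(df$se_y)) || any(df$se_y <= 0))
    stop("se_y must be positive")
  structure(df, class = c("harmonised_study", "data.frame"))
}

#' Harmonise exposure and outcome summary statistics
#'
#' Matches variants by ID and orients the outcome effect to the exposure's
#' effect allele: identical alleles pass through; swapped alleles flip the
#' sign of the outcome beta (and the outcome EAF); strand-complemented
#' alleles are complemented first. Palindromic variants (A/T, C/G) are
#' resolved by allele frequency when both studies' EAFs are at least
#' `freq_margin` from 0.5 (the 0.42/0.58 convention), else dropped. Variants
#' absent from the outcome study, or with irreconcilable alleles, are dropped
#' with the counts recorded in the `dropped` attribute.
#'
#' @param exposure_stats,outcome_stats data.frames with columns SNP,
#'   effect_allele, other_allele, beta, se and optionally eaf
#' @param freq_margin palindromic frequency bound (default 0.08)
#' @return a `harmonised_study` data.frame (SNP, bx, se_x, by, se_y, eaf)
#'   with attribute `dropped`
#' @export
harmonise <- function(exposure_stats, outcome_stats, freq_margin = 0.08) {
  req <- c("SNP", "effect_allele", "other_allele", "beta", "se")
  stopifnot(all(req %in% names(exposure_stats)),
            all(req %in% names(outcome_stats)))
  dropped <- data.frame(snp = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  m <- match(exposure_stats$SNP, outcome_stats$SNP)
  absent <- is.na(m)
  if (any(absent))
    dropped <- rbind(dropped, data.frame(snp = exposure_stats$SNP[absent],
                                         reason = "absent from outcome study",
                                         stringsAsFactors = FALSE))
  rows <- list()
  for (i in which(!absent)) {
    o <- outcome_stats[m[i], ]
    ea_x <- toupper(exposure_stats$effect_allele[i])
    oa_x <- toupper(exposure_stats$other_allele[i])
    ea_o <- toupper(o$effect_allele); oa_o <- toupper(o$other_allele)
    by <- o$beta
    if (is_palindromic(ea_x, oa_x)) {
      f_x <- exposure_stats$eaf[i] %||% NA_real_
      f_o <- o$eaf %||% NA_real_
      if (is.na(f_x) || is.na(f_o) || abs(f_x - 0.5) <= freq_margin ||
          abs(f_o - 0.5) <= freq_margin) {
        dropped <- rbind(dropped,
                         data.frame(snp = o$SNP,
                                    reason = "palindromic, frequency-unresolvable",
                                    stringsAsFactors = FALSE))
        next
      }
      if ((f_x > 0.5) != (f_o > 0.5)) by <- -by
    } else if (ea_x == ea_o && oa_x == oa_o) {
      # identity
    } else if (ea_x == oa_o && oa_x == ea_o) {
      by <- -by
    } else if (ea_x == .complement[ea_o] && oa_x == .complement[oa_o]) {
      # strand complement, same orientation
    } else if (ea_x == .complement[oa_o] && oa_x == .complement[ea_o]) {
      by <- -by
    } else {
      dropped <- rbind(dropped, data.frame(snp = o$SNP,
                                           reason = "alleles irreconcilable",
                                           stringsAsFactors = FALSE))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      SNP = exposure_stats$SNP[i], bx = exposure_stats$beta[i],
      se_x = exposure_stats$se[i], by = by, se_y = o$se,
      eaf = exposure_stats$eaf[i] %||% NA_real_, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("zero variants remain after harmonisation")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- new_harmonised_study(out)
  attr(out, "dropped") <- dropped
  out
}

#' Single-variant Wald ratio
#'
#' `estimate = by / bx` with first-order SE `se_y / |bx|`.
#'
#' @param bx exposure beta (nonzero)
#' @param by outcome beta
#' @param se_y outcome SE
#' @return list `estimate`, `se`
#' @export
wald_ratio <- function(bx, by, se_y) {
  if (bx == 0) stop("bx = 0: Wald ratio undefined")
  list(estimate = by / bx, se = se_y / abs(bx))
}

# weighted regression of by on bx (optionally with intercept) used by both
# IVW and Egger; returns coefficients, fixed-effect vcov and weighted RSS
wls_fit <- function(bx, by, w, intercept = FALSE) {
  X <- if (intercept) cbind(1, bx) else cbind(bx)
  XtWX <- crossprod(X, X * w)
  XtWy <- crossprod(X, by * w)
  beta <- solve(XtWX, XtWy)
  res <- by - drop(X %*% beta)
  list(beta = unname(drop(beta)), vcov_fe = unname(solve(XtWX)),
       rss_w = sum(w * res^2))
}

#' Inverse-variance weighted two-sample MR
#'
#' Weighted regression of the outcome betas on the exposure betas through the
#' origin, weights `1/se_y^2`, with a multiplicative random-effects SE: the
#' fixed-effect SE is scaled by `max(1, sqrt(Q/(k-1)))` so between-variant
#' heterogeneity inflates — but underdispersion never deflates — the SE.
#' P-value from the normal approximation.
#'
#' @param study a `harmonised_study`
#' @return an [mr_fit()] with method "IVW"; diagnostics hold `Q`, `k`,
#'   `phi` (the SE scale factor)
#' @export
ivw <- function(study) {
  k <- nrow(study)
  if (k < 2) stop("IVW needs >= 2 variants")
  w <- 1 / study$se_y^2
  f <- wls_fit(study$bx, study$by, w, intercept = FALSE)
  est <- f$beta[1]
  se_fe <- sqrt(f$vcov_fe[1, 1])
  Q <- f$rss_w
  phi <- max(1, sqrt(Q / (k - 1)))
  se <- se_fe * phi
  wald_fit(est, se, "IVW", diagnostics = list(Q = Q, k = k, phi = phi),
           n_cases = NA_integer_, n_controls = NA_integer_)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept (weights `1/se_y^2`), after reorienting every variant so
#' `bx >= 0` (flipping the (bx, by) pair jointly), which is required for the
#' intercept to capture directional pleiotropy. SEs use the multiplicative
#' random-effects scale `max(1, sqrt(Q/(k-2)))`; slope and intercept p-values
#' come from a t distribution with k-2 df.
#'
#' @param study a `harmonised_study` with k >= 3 variants
#' @return list of class `egger_fit`: slope, slope_se, slope_ci, slope_p,
#'   intercept, intercept_se, intercept_p, k, phi
#' @export
egger <- function(study) {
  k <- nrow(study)
  if (k < 3) stop("MR-Egger needs >= 3 variants")
  flip <- study$bx < 0
  bx <- ifelse(flip, -study$bx, study$bx)
  by <- ifelse(flip, -study$by, study$by)
  w <- 1 / study$se_y^2
  f <- wls_fit(bx, by, w, intercept = TRUE)
  phi <- max(1, sqrt(f$rss_w / (k - 2)))
  se <- sqrt(diag(f$vcov_fe)) * phi
  tstat <- f$beta / se
  p <- 2 * pt(abs(tstat), df = k - 2, lower.tail = FALSE)
  z <- stats::qt(0.975, df = k - 2)
  structure(list(slope = f$beta[2], slope_se = se[2],
                 slope_ci = exp(f$beta[2] + c(-1, 1) * z * se[2]),
                 slope_p = p[2],
                 intercept = f$beta[1], intercept_se = se[1],
                 intercept_p = max(p[1], .Machine$double.xmin),
                 k = k, phi = phi),
            class = "egger_fit")
}

#' @export
print.egger_fit <- function(x, ...) {
  cat(sprintf(
    "<egger_fit> OR %.3f [%.3f-%.3f], p = %s; intercept %.4f (p = %s), k = %d\n",
    exp(x$slope), x$slope_ci[1], x$slope_ci[2], fmt_p(x$slope_p),
    x$intercept, fmt_p(x$intercept_p), x$k))
  invisible(x)
}

#' Multivariable MR
#'
#' Direct effect of each exposure conditional on the others: weighted
#' multivariable regression (no intercept, weights `1/se_y^2`) of the outcome
#' betas on the matrix of exposure betas over the union of instruments.
#' Variants missing a beta for any exposure are dropped; duplicated variant
#' IDs are de-duplicated (first occurrence kept) with the count logged.
#' De-duplication is by variant identity only — no LD pruning is applied, and
#' every result carries that flag. SEs use the multiplicative random-effects
#' scale with k - p degrees of freedom.
#'
#' @param exposure_stats_list named list (>= 2) of exposure summary-stat
#'   data.frames (SNP, effect_allele, other_allele, beta, se, optionally eaf)
#' @param outcome_stats outcome summary-stat data.frame, same schema
#' @return list of class `mvmr_fit`: data.frame `estimates` (exposure,
#'   estimate, se, p), `k`, `n_duplicates_removed`, `ld_pruning` = "none"
#' @export
mvmr <- function(exposure_stats_list, outcome_stats) {
  p <- length(exposure_stats_list)
  if (p < 2) stop("MVMR needs >= 2 exposures")
  if (is.null(names(exposure_stats_list)))
    names(exposure_stats_list) <- paste0("exposure", seq_len(p))
  # union of instruments, de-duplicated by ID
  union_snps <- unique(unlist(lapply(exposure_stats_list, `[[`, "SNP")))
  n_dup <- sum(vapply(exposure_stats_list,
                      function(d) nrow(d), integer(1))) - length(union_snps)
  # harmonise each exposure to the outcome on the union
  harm <- lapply(exposure_stats_list, function(d) {
    h <- harmonise(d, outcome_stats)
    h[match(union_snps, h$SNP), , drop = FALSE]
  })
  # each exposure's beta must be available for every union variant; the
  # first exposure's harmonised outcome stats anchor by/se_y
  B <- sapply(harm, function(h) h$bx)
  by <- harm[[1]]$by
  se_y <- harm[[1]]$se_y
  for (h in harm[-1]) {
    i <- !is.na(h$by) & is.na(by)
    by[i] <- h$by[i]; se_y[i] <- h$se_y[i]
  }
  keep <- stats::complete.cases(B) & !is.na(by) & !is.na(se_y)
  B <- B[keep, , drop = FALSE]; by <- by[keep]; se_y <- se_y[keep]
  k <- nrow(B)
  if (k <= p) stop("too few variants with betas for all exposures")
  colnames(B) <- names(exposure_stats_list)
  # an exposure with identically-zero betas is unidentified but must not sink
  # the others (univariable reduction); it gets an NA estimate
  live <- colSums(B^2) > 0
  Bl <- B[, live, drop = FALSE]
  pl <- ncol(Bl)
  if (qr(Bl)$rank < pl) {
    cc <- stats::cor(Bl)
    bad <- which(abs(cc) > 0.999999 & row(cc) < col(cc), arr.ind = TRUE)
    nm <- colnames(Bl)
    stop("rank-deficient exposure-beta matrix; collinear exposures: ",
         if (nrow(bad)) paste(nm[bad[, 1]], nm[bad[, 2]], sep = " ~ ",
                              collapse = ", ") else "unknown pair")
  }
  w <- 1 / se_y^2
  XtWX <- crossprod(Bl, Bl * w)
  beta <- solve(XtWX, crossprod(Bl, by * w))
  res <- by - drop(Bl %*% beta)
  phi <- max(1, sqrt(sum(w * res^2) / (k - pl)))
  vc <- solve(XtWX) * phi^2
  est <- se <- rep(NA_real_, p)
  est[live] <- drop(beta)
  se[live] <- sqrt(diag(vc))
  structure(list(
    estimates = data.frame(
      exposure = names(exposure_stats_list), estimate = est, se = se,
      p = 2 * pnorm(abs(est / se), lower.tail = FALSE),
      stringsAsFactors = FALSE),
    k = k, n_duplicates_removed = n_dup, phi = phi,
    ld_pruning = "none (de-duplication by variant identity only)"),
    class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat(sprintf("<mvmr_fit> %d variants; LD pruning: %s\n", x$k, x$ld_pruning))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}
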