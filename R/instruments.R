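#' Construct an instrument set
#'
#' An instrument set is the definition of one exposure's genetic instrument:
#' variant IDs, effect/other alleles, per-allele weights on the exposure
#' scale, and (optionally) effect-allele frequencies used for harmonising
#' palindromic variants and for mean-imputing missing dosages.
#'
#' @param snp variant IDs
#' @param effect_allele,other_allele allele strings (upper-cased)
#' @param weight per-allele effect on the exposure
#' @param eaf effect-allele frequency in [0,1], or NA
#' @return data.frame of class `instrument_set`
#' @export
instrument_set <- function(snp, effect_allele, other_allele, weight,
                           eaf = NA_real_) {
  effect_allele <- toupper(effect_allele)
  other_allele <- toupper(other_allele)
  if (any(effect_allele == other_allele)) stop("alleles must differ")
  if (any(!is.finite(weight))) stop("weights must be finite")
  structure(data.frame(snp = snp, effect_allele = effect_allele,
                       other_allele = other_allele, weight = weight,
                       eaf = rep_len(eaf, length(snp)),
                       stringsAsFactors = FALSE),
            class = c("instrument_set", "data.frame"))
}

is_palindromic <- function(a, b) .complement[a] == b

#' Align cohort dosages to an instrument set's effect alleles
#'
#' For each instrument variant found in the cohort: if the cohort's effect
#' allele matches, the dosage is used as is; if the alleles are swapped, the
#' dosage is reflected (2 - dosage); if they match only after strand
#' complementation the same rules apply on the complemented alleles.
#' Palindromic variants (A/T, C/G) carry no strand information, so they are
#' resolved by allele frequency only when both the instrument EAF and the
#' cohort frequency are at least 0.08 away from 0.5 (the conventional
#' 0.42/0.58 bounds); otherwise they are dropped with a warning, as are
#' variants whose alleles cannot be reconciled at all. More than 50% of
#' instruments dropped is a hard error.
#'
#' @param cohort a `grsmr_cohort` (or any list with `dosages` and
#'   `variant_meta`)
#' @param iset an [instrument_set()]
#' @param freq_margin distance from 0.5 required to frequency-resolve a
#'   palindromic variant (default 0.08)
#' @return dosage matrix (participants x retained instruments) counted in
#'   effect-allele copies, with attributes `weights`, `eaf` and `dropped`
#'   (data.frame of snp + reason)
#' @export
align_dosages <- function(cohort, iset, freq_margin = 0.08) {
  stopifnot(inherits(iset, "instrument_set"))
  meta <- cohort$variant_meta
  dos <- cohort$dosages
  cols <- list(); w <- c(); eafs <- c()
  dropped <- data.frame(snp = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop_it <- function(s, r) rbind(dropped, data.frame(snp = s, reason = r,
                                                      stringsAsFactors = FALSE))
  for (i in seq_len(nrow(iset))) {
    s <- iset$snp[i]
    j <- match(s, meta$id)
    if (is.na(j)) { dropped <- drop_it(s, "absent from cohort"); next }
    ea_i <- iset$effect_allele[i]; oa_i <- iset$other_allele[i]
    ea_c <- toupper(meta$effect_allele[j]); oa_c <- toupper(meta$other_allele[j])
    d <- dos[, j]
    if (is_palindromic(ea_i, oa_i)) {
      f_i <- iset$eaf[i]
      f_c <- mean(d, na.rm = TRUE) / 2
      if (is.na(f_i) || abs(f_i - 0.5) <= freq_margin ||
          abs(f_c - 0.5) <= freq_margin) {
        dropped <- drop_it(s, "palindromic, frequency-unresolvable")
        next
      }
      # orient by frequency: cohort dosage counts whichever allele is at
      # frequency f_c; flip when the frequency classes disagree
      aligned <- if ((f_i > 0.5) == (f_c > 0.5)) d else 2 - d
    } else if (ea_i == ea_c && oa_i == oa_c) {
      aligned <- d
    } else if (ea_i == oa_c && oa_i == ea_c) {
      aligned <- 2 - d
    } else if (ea_i == .complement[ea_c] && oa_i == .complement[oa_c]) {
      aligned <- d
    } else if (ea_i == .complement[oa_c] && oa_i == .complement[ea_c]) {
      aligned <- 2 - d
    } else {
      dropped <- drop_it(s, "alleles irreconcilable")
      next
    }
    cols[[s]] <- aligned
    w <- c(w, iset$weight[i])
    eafs <- c(eafs, iset$eaf[i])
  }
  if (nrow(dropped) > 0)
    warning(sprintf("align_dosages: dropped %d instrument(s): %s",
                    nrow(dropped),
                    paste(dropped$snp, dropped$reason, sep = " - ",
                          collapse = "; ")))
  if (nrow(dropped) > nrow(iset) / 2)
    stop("more than 50% of instruments could not be aligned")
  out <- do.call(cbind, cols)
  attr(out, "weights") <- setNames(w, colnames(out))
  attr(out, "eaf") <- setNames(eafs, colnames(out))
  attr(out, "dropped") <- dropped
  out
}

#' Additive genetic risk score
#'
#' `score_i = sum_j weight_j * dosage_ij` over aligned dosages. Missing
#' dosages contribute `weight * 2 * eaf` (mean imputation) when the effect-
#' allele frequency is known, else the variant's observed mean dosage.
#'
#' @param aligned aligned dosage matrix from [align_dosages()], or any
#'   numeric matrix
#' @param weights per-variant weights; defaults to the matrix's `weights`
#'   attribute
#' @param eaf per-variant effect-allele frequencies for imputation; defaults
#'   to the matrix's `eaf` attribute
#' @return numeric score per participant
#' @export
compute_grs <- function(aligned, weights = attr(aligned, "weights"),
                        eaf = attr(aligned, "eaf")) {
  if (is.null(weights)) stop("weights required")
  stopifnot(length(weights) == ncol(aligned))
  if (anyNA(aligned)) {
    fill <- if (!is.null(eaf)) 2 * eaf else rep(NA_real_, ncol(aligned))
    for (j in seq_len(ncol(aligned))) {
      miss <- is.na(aligned[, j])
      if (any(miss)) {
        f <- fill[j]
        if (is.na(f)) f <- mean(aligned[, j], na.rm = TRUE)
        aligned[miss, j] <- f
      }
    }
  }
  drop(aligned %*% weights)
}

#' Instrument strength (R-squared and F-statistic)
#'
#' Simple linear regression of the exposure on the genetic risk score;
#' `F = (n - 2) R^2 / (1 - R^2)`, the single-predictor identity.
#'
#' @param grs genetic risk score
#' @param exposure exposure values (same length)
#' @return list of class `strength_result`: `r_squared`, `f_statistic`, `n`
#' @export
instrument_strength <- function(grs, exposure) {
  ok <- complete.cases(grs, exposure)
  grs <- grs[ok]; exposure <- exposure[ok]
  n <- length(grs)
  if (n < 3) stop("need >= 3 complete pairs")
  if (var(grs) == 0) stop("zero-variance GRS")
  r2 <- stats::cor(grs, exposure)^2
  if (1 - r2 < 1e-12) stop("R^2 = 1: F-statistic undefined")
  structure(list(r_squared = r2, f_statistic = (n - 2) * r2 / (1 - r2),
                 n = n), class = "strength_result")
}

#' @export
print.strength_result <- function(x, ...) {
  cat(sprintf("Instrument strength: R^2 = %.4g, F = %.4g, n = %d\n",
              x$r_squared, x$f_statistic, x$n))
  invisible(x)
}

#' Estimate instrument weights in-sample
#'
#' For instruments lacking external sex-stratified weights, re-estimate each
#' variant's per-allele effect by simple linear regression of the exposure on
#' dosage, per sex, among cancer-free participants only (to minimise
#' selection bias from the outcome). Monomorphic variants are dropped with
#' their weight missing.
#'
#' @param cohort a `grsmr_cohort`
#' @param snp_ids variants to estimate (default: all cohort variants)
#' @param exclude_mask logical per participant, TRUE = exclude (e.g. cancer
#'   flags)
#' @param sex sex label to restrict to
#' @param exposure_col phenotype column holding the exposure (default
#'   `exposure_raw`)
#' @return an [instrument_set()] with in-sample weights and EAFs
#' @export
estimate_weights_in_sample <- function(cohort, snp_ids = NULL, exclude_mask,
                                       sex, exposure_col = "exposure_raw") {
  phen <- cohort$phenotypes
  stopifnot(length(exclude_mask) == nrow(phen))
  use <- !exclude_mask & phen$sex == sex
  if (!any(use)) stop("exclusion mask removes all participants")
  if (is.null(snp_ids)) snp_ids <- cohort$variant_meta$id
  j <- match(snp_ids, cohort$variant_meta$id)
  if (anyNA(j)) stop("unknown variant id(s): ",
                     paste(snp_ids[is.na(j)], collapse = ", "))
  g <- cohort$dosages[use, j, drop = FALSE]
  x <- phen[[exposure_col]][use]
  keep <- apply(g, 2, function(v) var(v, na.rm = TRUE) > 0)
  if (!all(keep))
    warning(sprintf("dropping %d monomorphic variant(s)", sum(!keep)))
  g <- g[, keep, drop = FALSE]
  j <- j[keep]
  gc <- scale(g, center = TRUE, scale = FALSE)
  betas <- drop(crossprod(gc, x - mean(x))) / colSums(gc^2)
  meta <- cohort$variant_meta[j, , drop = FALSE]
  instrument_set(meta$id, meta$effect_allele, meta$other_allele,
                 weight = betas, eaf = colMeans(g) / 2)
}
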