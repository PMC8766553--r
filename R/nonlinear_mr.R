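#' Instrument-free exposure residuals
#'
#' Residuals of a linear regression of the exposure on the genetic risk
#' score, age, age-squared and, when supplied, the leading genetic principal
#' components and genotyping-array indicator. These residuals order
#' participants for the sliding-window analysis without using the part of
#' the exposure explained by the instrument.
#'
#' @param exposure exposure values
#' @param grs genetic risk score
#' @param age age at baseline (age^2 is added automatically)
#' @param pcs optional matrix of principal components (first four, typically)
#' @param array_indicator optional genotyping-array covariate
#' @return numeric residuals
#' @export
iv_free_residuals <- function(exposure, grs, age, pcs = NULL,
                              array_indicator = NULL) {
  X <- cbind(intercept = 1, grs = grs, age = age, age2 = age^2)
  if (!is.null(pcs)) X <- cbind(X, as.matrix(pcs))
  if (!is.null(array_indicator)) X <- cbind(X, array = array_indicator)
  ok <- complete.cases(X, exposure)
  if (!all(ok)) stop("complete cases required for residual computation")
  if (qr(X)$rank < ncol(X)) stop("collinear covariates in residual model")
  qx <- qr(X)
  drop(qr.resid(qx, exposure))
}

#' Sliding-window index ranges
#'
#' Over the residual-sorted order, windows are `[k*step + 1, k*step +
#' window_size]` for `k = 0 .. floor((n - window_size)/step)`, giving
#' `floor((n - window_size)/step) + 1` windows.
#'
#' @param n number of participants
#' @param window_size participants per window
#' @param step_size participants between successive window starts
#' @return list of integer ranges (each `start:end`)
#' @export
make_windows <- function(n, window_size, step_size) {
  if (step_size < 1 || window_size < step_size)
    stop("need 1 <= step_size <= window_size")
  if (n < window_size)
    stop(sprintf("n (%d) < window_size (%d): choose a smaller window",
                 n, window_size))
  n_win <- floor((n - window_size) / step_size) + 1
  lapply(seq_len(n_win) - 1L,
         function(k) (k * step_size + 1L):(k * step_size + window_size))
}

#' Sliding-window non-linear MR profile
#'
#' Orders participants by instrument-free residuals (ties broken by
#' participant ID for a stable sort), slides a fixed-size window, and
#' estimates a localized causal effect per window: the coefficient of the
#' GRS in a within-window logistic regression of the outcome on GRS and age,
#' divided by the GRS-exposure slope. The denominator is the whole-sample
#' stage-1 slope by default (stabler than per-window slopes, which can
#' approach zero); set `denominator = "window"` for the fully local variant.
#' SE by the delta method (denominator treated as fixed for the whole-sample
#' choice). Windows with zero cases get a missing estimate and a flag.
#'
#' @param exposure exposure values (standardised for per-SD estimates)
#' @param grs genetic risk score
#' @param case_status 0/1 outcome, prevalent cases already removed
#' @param age age at baseline
#' @param ids participant IDs for tie-breaking (default seq_along)
#' @param window_size,step_size window specification
#' @param pcs,array_indicator optional residual-model covariates
#' @param denominator "whole" (default) or "window" stage-1 slope
#' @return data.frame of class `window_profile`: window, start, end,
#'   mean_exposure, estimate, se, n_cases, flagged; attribute `denominator`
#' @export
window_profile <- function(exposure, grs, case_status, age,
                           ids = seq_along(exposure),
                           window_size, step_size,
                           pcs = NULL, array_indicator = NULL,
                           denominator = c("whole", "window")) {
  denominator <- match.arg(denominator)
  y <- check_outcome(case_status)
  res <- iv_free_residuals(exposure, grs, age, pcs, array_indicator)
  ord <- order(res, ids)
  xo <- exposure[ord]; go <- grs[ord]; yo <- y[ord]; ao <- age[ord]
  wins <- make_windows(length(xo), window_size, step_size)

  slope_of <- function(g, x) {
    gm <- g - mean(g)
    s <- sum(gm^2)
    if (s <= 0) return(NA_real_)
    sum(gm * (x - mean(x))) / s
  }
  denom_whole <- slope_of(go, xo)

  rows <- lapply(seq_along(wins), function(k) {
    i <- wins[[k]]
    out <- data.frame(window = k, start = i[1], end = i[length(i)],
                      mean_exposure = mean(xo[i]), estimate = NA_real_,
                      se = NA_real_, n_cases = sum(yo[i]), flagged = TRUE)
    if (sum(yo[i]) == 0 || var(go[i]) == 0) return(out)
    fit <- fast_logit(cbind(intercept = 1, grs = go[i], age = ao[i]), yo[i])
    if (!fit$converged) return(out)
    den <- if (denominator == "whole") denom_whole else slope_of(go[i], xo[i])
    if (!is.finite(den) || abs(den) < 1e-12) return(out)
    out$estimate <- fit$coef[["grs"]] / den
    out$se <- fit$se[["grs"]] / abs(den)
    out$flagged <- FALSE
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "denominator") <- denominator
  attr(out, "window_size") <- window_size
  attr(out, "step_size") <- step_size
  class(out) <- c("window_profile", "data.frame")
  out
}

#' Trend of localized estimates across the exposure range
#'
#' Inverse-variance-weighted regression of the window estimates on the
#' window-mean exposures. Overlapping windows are correlated, so the slope's
#' standard error is computed on the independent sub-profile by default:
#' windows spaced at least one full window apart, whose sampling errors share
#' no participants. The slope sign from the full profile is also reported
#' (valid without independence).
#'
#' @param profile a `window_profile`
#' @param independent_only use only non-overlapping windows for the SE
#'   (default TRUE)
#' @return list: `slope`, `se`, `z`, `n_windows_used`, `full_profile_slope`
#' @export
profile_trend <- function(profile, independent_only = TRUE) {
  ok <- !profile$flagged & is.finite(profile$estimate) &
    is.finite(profile$se) & profile$se > 0
  pf <- profile[ok, , drop = FALSE]
  wls_slope <- function(d) {
    w <- 1 / d$se^2
    x <- d$mean_exposure; yv <- d$estimate
    xm <- sum(w * x) / sum(w)
    sxx <- sum(w * (x - xm)^2)
    slope <- sum(w * (x - xm) * yv) / sxx
    list(slope = slope, se = sqrt(1 / sxx))
  }
  full <- wls_slope(pf)
  use <- pf
  if (independent_only) {
    spacing <- ceiling(attr(profile, "window_size") /
                         attr(profile, "step_size"))
    use <- pf[pf$window %in% seq(min(pf$window), max(pf$window),
                                 by = spacing), , drop = FALSE]
  }
  if (nrow(use) < 3) stop("too few windows for a trend test")
  ind <- wls_slope(use)
  list(slope = ind$slope, se = ind$se, z = ind$slope / ind$se,
       n_windows_used = nrow(use), full_profile_slope = full$slope)
}

#' Plot a non-linear MR window profile
#'
#' Localized estimate against window-mean exposure with a pointwise 95%
#' confidence band.
#'
#' @param x a `window_profile`
#' @param ... passed to [graphics::plot()]
#' @return invisibly, `x`
#' @export
plot.window_profile <- function(x, ...) {
  ok <- !x$flagged
  est <- x$estimate[ok]; se <- x$se[ok]; mx <- x$mean_exposure[ok]
  lo <- est - 1.96 * se; hi <- est + 1.96 * se
  graphics::plot(mx, est, type = "n", ylim = range(lo, hi),
                 xlab = "window mean exposure",
                 ylab = "localized log-OR per SD", ...)
  graphics::polygon(c(mx, rev(mx)), c(lo, rev(hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(mx, est, lwd = 2, col = "steelblue4")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
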