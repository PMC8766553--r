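#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' A single pipeline seed streams into independent per-stage substreams so
#' that, e.g., genotype simulation and bootstrap resampling are individually
#' reproducible no matter which stages run. The label is hashed to a 31-bit
#' offset; results always fit in an R integer.
#'
#' @param seed master integer seed
#' @param label character stage label
#' @return an integer seed
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Fast logistic fit wrapper around the compiled IRLS; returns coef/se/vcov
# with names taken from the design matrix columns.
fast_logit <- function(X, y) {
  fit <- cpp_logit(X, as.numeric(y))
  cf <- drop(fit$coef)
  se <- drop(fit$se)
  names(cf) <- names(se) <- colnames(X)
  list(coef = cf, se = se, vcov = fit$vcov, converged = fit$converged)
}

fmt_p <- function(p) formatC(p, format = "e", digits = 2)

`%||%` <- function(a, b) if (is.null(a)) b else a
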