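#' Screen candidate confounders
#'
#' A candidate column is eligible when it has more than `min_nonmissing`
#' non-missing observations, is associated with the exposure (simple linear
#' regression, p < `alpha`) and with the outcome (logistic regression
#' adjusted for age, p < `alpha`). Categorical candidates are first expanded
#' into one binary indicator per level (named `column.level`).
#'
#' @param table data.frame of candidate columns plus the exposure, outcome
#'   and age columns
#' @param exposure_col,outcome_col,age_col column names
#' @param candidates candidate column names (default: everything else)
#' @param alpha association threshold (default 0.05)
#' @param min_nonmissing required non-missing count (default 1000, exclusive)
#' @return data.frame report (candidate, n_nonmissing, p_exposure,
#'   p_outcome, eligible); eligible names in attribute `eligible`
#' @export
screen_candidates <- function(table, exposure_col, outcome_col,
                              age_col = "age", candidates = NULL,
                              alpha = 0.05, min_nonmissing = 1000) {
  if (is.null(candidates))
    candidates <- setdiff(names(table),
                          c(exposure_col, outcome_col, age_col))
  # expand categorical candidates to binary indicators
  expanded <- list()
  for (nm in candidates) {
    v <- table[[nm]]
    if (is.numeric(v)) {
      expanded[[nm]] <- v
    } else {
      v <- as.character(v)
      for (lev in sort(unique(v[!is.na(v)]))) {
        expanded[[paste(nm, lev, sep = ".")]] <-
          ifelse(is.na(v), NA_real_, as.numeric(v == lev))
      }
    }
  }
  x <- table[[exposure_col]]
  y <- table[[outcome_col]]
  age <- table[[age_col]]
  rows <- lapply(names(expanded), function(nm) {
    v <- expanded[[nm]]
    n_ok <- sum(!is.na(v))
    p_x <- p_y <- NA_real_
    if (n_ok > min_nonmissing && var(v, na.rm = TRUE) > 0) {
      ok <- !is.na(v) & !is.na(x)
      # suppressWarnings: a candidate that is an exact copy of the exposure
      # fits perfectly and base R warns, but the p-value (0) is what we need
      sf <- suppressWarnings(summary(lm(x[ok] ~ v[ok])))
      p_x <- sf$coefficients["v[ok]", 4]
      ok2 <- !is.na(v) & !is.na(y) & !is.na(age)
      gf <- tryCatch(fast_logit(cbind(1, v = v[ok2], age = age[ok2]), y[ok2]),
                     error = function(e) NULL)
      if (!is.null(gf) && gf$converged)
        p_y <- 2 * pnorm(abs(gf$coef[[2]] / gf$se[[2]]), lower.tail = FALSE)
    }
    data.frame(candidate = nm, n_nonmissing = n_ok, p_exposure = p_x,
               p_outcome = p_y,
               eligible = n_ok > min_nonmissing & !is.na(p_x) &
                 !is.na(p_y) & p_x < alpha & p_y < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "eligible") <- out$candidate[out$eligible]
  attr(out, "expanded") <- expanded
  out
}

#' Stepwise confounder-attenuation search
#'
#' Greedy forward selection of covariates that minimise the exposure's
#' effect size on the outcome. At each step every remaining candidate is
#' added in turn to `outcome ~ exposure + age + selected`, and the candidate
#' yielding the smallest |ln(OR)| of the exposure is accepted — provided the
#' relative reduction exceeds `tolerance`. Age is in every model. Each model
#' is fit on its own complete cases with the n logged. Ties break
#' lexicographically by candidate name; non-converging candidates are
#' skipped for that step.
#'
#' @param table data.frame holding all columns
#' @param exposure_col,outcome_col,age_col column names
#' @param candidates candidate column names (screen first with
#'   [screen_candidates()]); may be an expanded-indicator list from the
#'   screen's `expanded` attribute
#' @param tolerance minimum relative reduction in |ln(OR)| to accept a step
#'   (default 0.01)
#' @return list of class `search_trace`: `initial` (ln_or, se, n), `steps`
#'   data.frame (step, covariate, ln_or, se, n, reduction), `stop_reason`
#' @export
stepwise_attenuation <- function(table, exposure_col, outcome_col,
                                 age_col = "age", candidates,
                                 tolerance = 0.01) {
  x <- table[[exposure_col]]
  y <- table[[outcome_col]]
  age <- table[[age_col]]
  cand_data <- if (is.list(candidates) && !is.null(names(candidates)) &&
                   !is.character(candidates)) candidates
  else setNames(lapply(candidates, function(nm) table[[nm]]), candidates)

  fit_lnor <- function(extra_cols) {
    M <- cbind(exposure = x, age = age)
    for (nm in names(extra_cols)) M <- cbind(M, extra_cols[[nm]])
    ok <- complete.cases(M, y)
    X <- cbind(intercept = 1, M[ok, , drop = FALSE])
    f <- tryCatch(fast_logit(X, y[ok]), error = function(e) NULL)
    if (is.null(f) || !f$converged) return(NULL)
    list(ln_or = unname(f$coef[2]), se = unname(f$se[2]), n = sum(ok))
  }

  base <- fit_lnor(list())
  if (is.null(base)) stop("baseline model did not converge")
  selected <- list()
  remaining <- sort(names(cand_data))
  steps <- data.frame(step = integer(0), covariate = character(0),
                      ln_or = numeric(0), se = numeric(0), n = integer(0),
                      reduction = numeric(0), stringsAsFactors = FALSE)
  current <- base
  stop_reason <- if (length(remaining) == 0) "no candidates" else NULL
  step_i <- 0L
  while (is.null(stop_reason)) {
    best <- NULL
    for (nm in remaining) {  # lexicographic order; strict < keeps first tie
      f <- fit_lnor(c(selected, cand_data[nm]))
      if (is.null(f)) next
      if (is.null(best) || abs(f$ln_or) < abs(best$fit$ln_or))
        best <- list(name = nm, fit = f)
    }
    if (is.null(best)) { stop_reason <- "no candidate model converged"; break }
    reduction <- (abs(current$ln_or) - abs(best$fit$ln_or)) /
      abs(current$ln_or)
    if (!is.finite(reduction) || reduction <= tolerance) {
      stop_reason <- "no candidate reduces |ln(OR)| beyond tolerance"
      break
    }
    step_i <- step_i + 1L
    selected <- c(selected, cand_data[best$name])
    remaining <- setdiff(remaining, best$name)
    steps <- rbind(steps, data.frame(
      step = step_i, covariate = best$name, ln_or = best$fit$ln_or,
      se = best$fit$se, n = best$fit$n, reduction = reduction,
      stringsAsFactors = FALSE))
    current <- best$fit
    if (length(remaining) == 0) stop_reason <- "candidates exhausted"
  }
  structure(list(initial = base, steps = steps, stop_reason = stop_reason),
            class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf("<search_trace> initial ln(OR) = %.4f (n = %d); %d step(s); stop: %s\n",
              x$initial$ln_or, x$initial$n, nrow(x$steps), x$stop_reason))
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}
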