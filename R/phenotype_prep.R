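#' Derive case/control/excluded status from diagnosis records
#'
#' A participant with at least one record whose code starts with
#' `invasive_code` is a case; one with an in-situ record (`insitu_code`
#' prefix) and no invasive record is excluded; anyone else is a control.
#' Matching is by code prefix, so "C50" matches "C50" and "C509". Records for
#' participants of the wrong sex are ignored with a warning.
#'
#' @param records long-format data.frame with columns `id`, `code`, `date`
#' @param participants data.frame with columns `id`, `sex`
#' @param sex sex label the outcome applies to ("F" or "M")
#' @param invasive_code invasive ICD-10-style prefix (e.g. "C50" or "C61")
#' @param insitu_code in-situ prefix (e.g. "D05" or "D075")
#' @return data.frame `id`, `status` (case/control/excluded),
#'   `diagnosis_date` (earliest invasive record date; NA otherwise)
#' @export
derive_cases <- function(records, participants, sex, invasive_code,
                         insitu_code) {
  stopifnot(all(c("id", "code") %in% names(records)),
            all(c("id", "sex") %in% names(participants)))
  if (any(!nzchar(records$code))) stop("empty diagnosis code")
  sex_ok <- participants$id[participants$sex == sex]
  wrong <- !(records$id %in% sex_ok) & records$id %in% participants$id
  if (any(wrong)) {
    warning(sprintf("ignoring %d diagnosis record(s) for wrong-sex participant(s)",
                    sum(wrong)))
    records <- records[!wrong, , drop = FALSE]
  }
  inv <- records[startsWith(records$code, invasive_code), , drop = FALSE]
  ins <- records[startsWith(records$code, insitu_code), , drop = FALSE]
  ids <- participants$id[participants$sex == sex]
  status <- rep("control", length(ids))
  status[ids %in% ins$id] <- "excluded"
  status[ids %in% inv$id] <- "case"
  ddate <- rep(as.Date(NA), length(ids))
  if (nrow(inv) > 0) {
    if (is.null(inv$date)) stop("invasive records lack a date column")
    first <- tapply(as.Date(inv$date), inv$id, function(d)
      if (all(is.na(d))) as.Date(NA) else min(d, na.rm = TRUE))
    m <- match(ids, names(first))
    ddate[!is.na(m)] <- as.Date(unlist(first[m[!is.na(m)]]),
                                origin = "1970-01-01")
  }
  data.frame(id = ids, status = status, diagnosis_date = ddate,
             stringsAsFactors = FALSE)
}

#' Remove prevalent cases from an analysis sample
#'
#' Cases whose earliest qualifying diagnosis predates `baseline_date` are
#' removed (row dropped). Cases with a missing diagnosis date cannot be
#' classified and are also removed, with a warning. Controls are untouched.
#' The operation is idempotent.
#'
#' @param sample data.frame containing `status` and `diagnosis_date`
#' @param baseline_date the baseline assessment date
#' @return the filtered data.frame, with attribute `n_removed`
#' @export
filter_incident <- function(sample, baseline_date) {
  stopifnot(all(c("status", "diagnosis_date") %in% names(sample)))
  baseline_date <- as.Date(baseline_date)
  is_case <- sample$status == "case"
  no_date <- is_case & is.na(sample$diagnosis_date)
  if (any(no_date))
    warning(sprintf("excluding %d case(s) with missing diagnosis date",
                    sum(no_date)))
  prevalent <- is_case & !is.na(sample$diagnosis_date) &
    sample$diagnosis_date < baseline_date
  out <- sample[!(prevalent | no_date), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(prevalent | no_date)
  out
}

#' Derive pre/post menopause stratum labels
#'
#' Cases are classified against their age at first diagnosis: `pre` if the
#' diagnosis occurred before menopause (reported menopause age greater than
#' the diagnosis age, or menopause not yet occurred at diagnosis), otherwise
#' `post`. Controls carry their baseline menopause status. Anything
#' indeterminate is `unknown`.
#'
#' @param status case/control/excluded vector
#' @param age_at_diagnosis numeric, cases only (NA otherwise)
#' @param menopause_age reported age at menopause (NA if unreported or not
#'   yet occurred)
#' @param baseline_status baseline menopause status for controls
#'   ("pre"/"post"/NA)
#' @return character vector of labels in {pre, post, unknown}
#' @export
derive_menopause_stratum <- function(status, age_at_diagnosis, menopause_age,
                                     baseline_status) {
  n <- length(status)
  out <- rep("unknown", n)
  ctrl <- status == "control"
  out[ctrl & !is.na(baseline_status)] <- baseline_status[ctrl & !is.na(baseline_status)]
  case <- status == "case"
  known <- case & !is.na(age_at_diagnosis) & !is.na(menopause_age)
  out[known & age_at_diagnosis < menopause_age] <- "pre"
  out[known & age_at_diagnosis >= menopause_age] <- "post"
  # menopause age unreported because not yet occurred: if baseline status is
  # pre and diagnosis is post-baseline, the case was pre-menopausal at diagnosis
  nr <- case & is.na(menopause_age) & !is.na(baseline_status) &
    baseline_status == "pre"
  out[nr] <- "pre"
  out
}

#' Derive the workplace chemical-exposure stratum
#'
#' `frequent` if any of the occupational-exposure answers is "Often" or
#' "Sometimes" at least once across the fields; `infrequent` if at least one
#' field was answered and none qualifies; `unknown` if all fields are missing.
#'
#' @param answers data.frame (or matrix) of answer strings, one column per
#'   workplace field, NA for missing
#' @return character vector in {frequent, infrequent, unknown}
#' @export
derive_chemical_exposure <- function(answers) {
  answers <- as.data.frame(answers, stringsAsFactors = FALSE)
  m <- as.matrix(answers)
  hit <- matrix(m %in% c("Often", "Sometimes"), nrow = nrow(m))
  any_hit <- rowSums(hit) > 0
  any_ans <- rowSums(!is.na(m)) > 0
  ifelse(any_hit, "frequent", ifelse(any_ans, "infrequent", "unknown"))
}

#' Waist-to-hip ratio
#'
#' @param wc waist circumference (cm)
#' @param hc hip circumference (cm)
#' @return wc/hc; NA where hc is missing or non-positive
#' @export
compute_whr <- function(wc, hc) {
  out <- ifelse(!is.na(hc) & hc > 0, wc / hc, NA_real_)
  out
}

#' Standardise a numeric column to mean 0, variance 1
#'
#' Mean and SD are computed over non-missing entries; missing values stay
#' missing.
#'
#' @param values numeric vector
#' @return z-scores, with attributes `center` and `scale`
#' @export
standardise <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need >= 2 non-missing values")
  m <- mean(values[ok])
  s <- sd(values[ok])
  if (s == 0) stop("zero variance: cannot standardise")
  out <- (values - m) / s
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

#' Variant quality filter on MAF and imputation INFO
#'
#' Keeps variants with minor allele frequency >= 0.01 and, for imputed
#' variants (INFO present), INFO >= 0.8. Genotyped variants (INFO missing)
#' are exempt from the INFO rule. Idempotent.
#'
#' @param variants data.frame with columns `maf` and optionally `info`
#' @param maf_min MAF threshold (default 0.01)
#' @param info_min INFO threshold (default 0.8)
#' @return the retained rows, attribute `n_removed`
#' @export
filter_variants <- function(variants, maf_min = 0.01, info_min = 0.8) {
  stopifnot("maf" %in% names(variants))
  info <- if ("info" %in% names(variants)) variants$info else
    rep(NA_real_, nrow(variants))
  keep <- variants$maf >= maf_min & (is.na(info) | info >= info_min)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}
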