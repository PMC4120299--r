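# Practice-level smoking prevalence estimators.
#
# The register-based estimator divides the published count of recorded
# current smokers (the cessation indicator's denominator, SM08 den) by the
# published eligible population aged 15+ (the status indicator's
# denominator, SM07 den). Because the numerator counts only *recorded*
# smokers while the denominator is the full eligible population, the
# estimator's expectation is r_s * p where r_s is the recording probability
# for smokers and p the true prevalence: with incomplete recording it is
# biased downward, whatever the non-smoker recording rate. The companion
# recorded-ratio estimator (SM08 den / SM07 num) is unbiased when recording
# is independent of smoking status; both are exposed.

#' Register-based smoking prevalence estimate
#'
#' Recorded current smokers (cessation-indicator denominator) divided by
#' the eligible population aged 15+ (status-indicator denominator). This is
#' the primary published-data estimator.
#'
#' @param cessation_denominator count of recorded current smokers.
#' @param status_denominator count of eligible patients aged 15 and over.
#' @return full-precision proportion; use [render_percent()] for display.
#' @examples
#' render_percent(estimate_prevalence(1129, 3721)) # 30.3
#' @export
estimate_prevalence <- function(cessation_denominator, status_denominator) {
  check_count(cessation_denominator, "cessation_denominator")
  check_count(status_denominator, "status_denominator")
  if (any(status_denominator == 0, na.rm = TRUE)) {
    stop_qof("undefined estimate: status denominator is zero",
             class = "qofprev_undefined_estimate")
  }
  bad <- !is.na(cessation_denominator) & !is.na(status_denominator) &
    cessation_denominator > status_denominator
  if (any(bad)) {
    stop_qof("recorded smokers exceed the eligible population",
             class = "qofprev_invariant")
  }
  cessation_denominator / status_denominator
}

#' Underlying achievement of an indicator
#'
#' Numerator over denominator before any payment threshold is applied.
#'
#' @param numerator indicator numerator count.
#' @param denominator indicator denominator count (> 0).
#' @return full-precision proportion.
#' @examples
#' render_percent(underlying_achievement(3450, 3721)) # 92.7
#' @export
underlying_achievement <- function(numerator, denominator) {
  check_count(numerator, "numerator")
  check_count(denominator, "denominator")
  if (any(denominator == 0, na.rm = TRUE)) {
    stop_qof("undefined achievement: denominator is zero",
             class = "qofprev_undefined_estimate")
  }
  if (any(numerator > denominator, na.rm = TRUE)) {
    stop_qof("numerator exceeds denominator", class = "qofprev_invariant")
  }
  numerator / denominator
}

#' List-based prevalence variant
#'
#' Recorded current smokers divided by the registered population aged 15+.
#' The fallback once the general status-recording indicator was retired
#' (2014/15 on): with incomplete recording it is biased downward relative
#' to [estimate_prevalence()] because the registered list exceeds the
#' indicator-eligible population.
#'
#' @param cessation_denominator count of recorded current smokers.
#' @param registered_population_15plus registered list size aged 15+ (> 0).
#' @return full-precision proportion.
#' @export
list_based_prevalence <- function(cessation_denominator,
                                  registered_population_15plus) {
  check_count(cessation_denominator, "cessation_denominator")
  check_count(registered_population_15plus, "registered_population_15plus")
  if (any(registered_population_15plus == 0, na.rm = TRUE)) {
    stop_qof("undefined estimate: registered population is zero",
             class = "qofprev_undefined_estimate")
  }
  cessation_denominator / registered_population_15plus
}

#' Prevalence among patients with a recorded status
#'
#' Recorded current smokers divided by patients whose status is recorded
#' (cessation denominator / status *numerator*). Unbiased for the true
#' prevalence when recording is independent of smoking status (MCAR),
#' unlike [estimate_prevalence()]; used in the bias analyses.
#'
#' @param cessation_denominator count of recorded current smokers.
#' @param status_numerator count of patients with smoking status recorded.
#' @return full-precision proportion.
#' @export
prevalence_among_recorded <- function(cessation_denominator,
                                      status_numerator) {
  check_count(cessation_denominator, "cessation_denominator")
  check_count(status_numerator, "status_numerator")
  if (any(status_numerator == 0, na.rm = TRUE)) {
    stop_qof("undefined estimate: no statuses recorded",
             class = "qofprev_undefined_estimate")
  }
  if (any(cessation_denominator > status_numerator, na.rm = TRUE)) {
    stop_qof("recorded smokers exceed recorded statuses",
             class = "qofprev_invariant")
  }
  cessation_denominator / status_numerator
}

#' Derive all practice-level estimates from indicator records
#'
#' For each practice-year computes the general and chronic prevalence
#' estimates, the underlying achievements of the status and cessation
#' indicators, and the chronic-condition share of the eligible population
#' (chronic status denominator / general status denominator). Chronic
#' fields are `NA` exactly when the source indicators are absent.
#'
#' @param records a validated `qof_records` data frame.
#' @param variant `"status-denominator"` (default, the published-method
#'   estimator) or `"list-based"`, in which case `list_size` must be a
#'   numeric vector of registered 15+ populations aligned with `records`.
#' @param list_size registered populations for the list-based variant.
#' @return data frame of class `practice_estimates` with columns
#'   `practice_id`, `year`, `prevalence_general`, `prevalence_chronic`,
#'   `ua_status_general`, `ua_status_chronic`, `ua_cessation_general`,
#'   `ua_cessation_chronic`, `chronic_share`, `status_denominator`.
#' @export
derive_practice_estimates <- function(records,
                                      variant = c("status-denominator",
                                                  "list-based"),
                                      list_size = NULL) {
  variant <- match.arg(variant)
  validate_qof_records(records)
  if (variant == "status-denominator" && any(records$sm07_den == 0, na.rm = TRUE)) {
    bad <- records$practice_id[!is.na(records$sm07_den) & records$sm07_den == 0]
    stop_qof("undefined estimate (zero eligible population) for practice(s): ",
             paste(bad, collapse = ", "),
             class = "qofprev_undefined_estimate")
  }
  ratio <- function(num, den) ifelse(!is.na(num) & !is.na(den) & den > 0,
                                     num / den, NA_real_)
  gen_den <- if (variant == "list-based") {
    stopifnot(!is.null(list_size), length(list_size) == nrow(records))
    list_size
  } else {
    records$sm07_den
  }
  out <- data.frame(
    practice_id = records$practice_id,
    year = records$year,
    prevalence_general = ratio(records$sm08_den, gen_den),
    prevalence_chronic = ratio(records$sm06_den, records$sm05_den),
    ua_status_general = ratio(records$sm07_num, records$sm07_den),
    ua_status_chronic = ratio(records$sm05_num, records$sm05_den),
    ua_cessation_general = ratio(records$sm08_num, records$sm08_den),
    ua_cessation_chronic = ratio(records$sm06_num, records$sm06_den),
    chronic_share = ratio(records$sm05_den, records$sm07_den),
    status_denominator = records$sm07_den,
    stringsAsFactors = FALSE
  )
  class(out) <- c("practice_estimates", "data.frame")
  out
}

#' Reshape yearly estimates into a practices-by-years matrix
#'
#' Helper for [yearly_concordance()]: rows are practices, columns years;
#' errors if any practice-year cell is missing (apply
#' [filter_complete_series()] first).
#'
#' @param estimates a `practice_estimates` data frame spanning >= 2 years.
#' @param measure which column to spread (default `"prevalence_chronic"`).
#' @return numeric matrix with practice ids as rownames, years as colnames.
#' @export
prevalence_matrix <- function(estimates, measure = "prevalence_chronic") {
  stopifnot(measure %in% names(estimates))
  years <- sort(unique(estimates$year))
  ids <- sort(unique(estimates$practice_id))
  m <- matrix(NA_real_, length(ids), length(years),
              dimnames = list(ids, years))
  idx <- cbind(match(estimates$practice_id, ids),
               match(estimates$year, years))
  m[idx] <- estimates[[measure]]
  if (anyNA(m)) {
    stop_qof("practice sets are misaligned across years",
             class = "qofprev_misaligned")
  }
  m
}
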