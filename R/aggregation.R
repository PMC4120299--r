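# Practice-to-district linkage and area-level aggregation.

#' Assign practices to local-authority districts
#'
#' Looks each practice's postcode up in an NSPD-style lookup. Whole-practice
#' assignment: a practice belongs entirely to the district of its own
#' postcode (no apportionment of the list across boundaries).
#'
#' @param records a `qof_records` data frame with postcodes.
#' @param lookup named character vector (postcode -> district code), as
#'   returned by [read_postcode_lookup()].
#' @return named character vector mapping `practice_id` to district code.
#'   Any unmatched postcode aborts with an error listing every unmatched
#'   practice (no silent drop).
#' @export
assign_districts <- function(records, lookup) {
  prac <- unique(records[, c("practice_id", "postcode")])
  if (anyDuplicated(prac$practice_id)) {
    stop_qof("practice(s) with conflicting postcodes across records: ",
             paste(unique(prac$practice_id[duplicated(prac$practice_id)]),
                   collapse = ", "),
             class = "qofprev_bad_value")
  }
  pc <- normalize_postcode(prac$postcode)
  dist <- lookup[pc]
  unmatched <- is.na(prac$postcode) | !(pc %in% names(lookup))
  if (any(unmatched)) {
    stop_qof("postcode not in lookup for practice(s): ",
             paste(prac$practice_id[unmatched], collapse = ", "),
             class = "qofprev_unmatched_postcode")
  }
  stats::setNames(unname(dist), prac$practice_id)
}

new_district_aggregate <- function(df, total = NULL) {
  class(df) <- c("district_aggregate", "data.frame")
  attr(df, "grand_total") <- total
  df
}

#' Pooled-count aggregation of practice records to districts
#'
#' Per district, sums the recorded-smoker counts (`sm08_den`) and eligible
#' populations (`sm07_den`) across member practices and divides — the
#' pooled estimator, equivalent to a denominator-weighted mean of practice
#' prevalences. A grand-total aggregate over every practice is attached as
#' attribute `"grand_total"`.
#'
#' @param records a validated `qof_records` data frame (one year).
#' @param assignment named vector practice_id -> district code covering
#'   every practice in `records`.
#' @return a `district_aggregate` data frame: `district_code`,
#'   `n_practices`, `pooled_status_denominator`, `pooled_smokers`,
#'   `prevalence`.
#' @export
aggregate_pooled <- function(records, assignment) {
  validate_qof_records(records)
  if (!all(records$practice_id %in% names(assignment))) {
    stop_qof("assignment does not cover practice(s): ",
             paste(setdiff(records$practice_id, names(assignment)),
                   collapse = ", "),
             class = "qofprev_unmatched_postcode")
  }
  dist <- unname(assignment[records$practice_id])
  smk <- tapply(records$sm08_den, dist, sum)
  den <- tapply(records$sm07_den, dist, sum)
  npr <- tapply(records$practice_id, dist, function(x) length(unique(x)))
  if (any(den == 0, na.rm = TRUE)) {
    stop_qof("district(s) with zero pooled eligible population: ",
             paste(names(den)[den == 0], collapse = ", "),
             class = "qofprev_undefined_estimate")
  }
  out <- data.frame(district_code = names(den),
                    n_practices = as.integer(npr),
                    pooled_status_denominator = as.integer(den),
                    pooled_smokers = as.integer(smk),
                    prevalence = as.numeric(smk / den),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  total <- data.frame(district_code = "TOTAL",
                      n_practices = length(unique(records$practice_id)),
                      pooled_status_denominator = sum(records$sm07_den),
                      pooled_smokers = sum(records$sm08_den),
                      prevalence = sum(records$sm08_den) / sum(records$sm07_den),
                      stringsAsFactors = FALSE)
  new_district_aggregate(out, total)
}

#' Mean-of-prevalences aggregation (sensitivity variant)
#'
#' Unweighted or denominator-weighted mean of practice prevalence
#' estimates per district. With `weights = "status_denominator"` the result
#' equals [aggregate_pooled()] exactly (algebraic identity).
#'
#' @param estimates a `practice_estimates` data frame (one year).
#' @param assignment named vector practice_id -> district code.
#' @param weights `"none"` or `"status_denominator"`.
#' @return a `district_aggregate` data frame (pooled count columns are the
#'   sums over member practices; `prevalence` is the chosen mean).
#' @export
aggregate_mean <- function(estimates, assignment,
                           weights = c("none", "status_denominator")) {
  weights <- match.arg(weights)
  if (!all(estimates$practice_id %in% names(assignment))) {
    stop_qof("assignment does not cover practice(s): ",
             paste(setdiff(estimates$practice_id, names(assignment)),
                   collapse = ", "),
             class = "qofprev_unmatched_postcode")
  }
  if (nrow(estimates) == 0) {
    stop_qof("no estimates to aggregate", class = "qofprev_undefined_estimate")
  }
  dist <- unname(assignment[estimates$practice_id])
  w <- if (weights == "none") rep(1, nrow(estimates)) else
    estimates$status_denominator
  p <- estimates$prevalence_general
  num <- tapply(w * p, dist, sum)
  den <- tapply(w, dist, sum)
  npr <- tapply(estimates$practice_id, dist, function(x) length(unique(x)))
  pool_den <- tapply(estimates$status_denominator, dist, sum)
  out <- data.frame(district_code = names(num),
                    n_practices = as.integer(npr),
                    pooled_status_denominator = as.integer(pool_den),
                    pooled_smokers = NA_integer_,
                    prevalence = as.numeric(num / den),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  total <- data.frame(district_code = "TOTAL",
                      n_practices = length(unique(estimates$practice_id)),
                      pooled_status_denominator = sum(estimates$status_denominator),
                      pooled_smokers = NA_integer_,
                      prevalence = sum(w * p) / sum(w),
                      stringsAsFactors = FALSE)
  new_district_aggregate(out, total)
}
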