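# Synthetic QOF-like registry generator with known ground truth.
#
# The generator states a world calibrated to the published summaries of an
# East Midlands practice cohort: 215 practices across 16 districts, a
# practice prevalence distribution centred near 19% with spread reaching
# roughly 6-43%, chronic-condition smoking about 3 percentage points below
# the general population, status recording near 88% (general) and 97%
# (chronic), and district survey samples of a few hundred respondents.
# A single global seed expands into fixed per-stream substreams (registry,
# survey, mortality, per-year) so stages can be regenerated independently.

# Table-calibrated district practice-count weights (16 districts)
DISTRICT_WEIGHTS <- c(9, 24, 8, 12, 2, 14, 9, 5, 8, 8, 9, 27, 8, 9, 59, 4)

substream <- function(seed, offset) {
  (as.integer(seed) * 1000L + as.integer(offset)) %% .Machine$integer.max
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults state the emulated world; they are scenario parameters, not
#' tuning dials. Prevalence is Beta-distributed with mean 0.19 and enough
#' spread that 215 draws range over roughly 0.06-0.40; list sizes are
#' log-normal around a 5500-patient eligible population; recording
#' probabilities match the published median underlying achievements
#' (88.1% general, 96.6% chronic); the chronic smoking offset is -3.05
#' percentage points.
#'
#' @param n_practices,n_districts cohort dimensions.
#' @param seed global seed; fully determines every generated artifact.
#' @param list_size log-normal parameters for the eligible population.
#' @param true_prevalence Beta parameters for practice smoking prevalence.
#' @param chronic_share Beta parameters for the chronic-register share of
#'   the eligible population.
#' @param chronic_smoking_offset signed shift (proportion scale) applied
#'   to a practice's prevalence in its chronic register.
#' @param recording list: `probability_general`, `probability_chronic`,
#'   `mar_log_odds_shift` (log-odds shift of the recording probability for
#'   smokers; 0 = MCAR, negative = smokers less likely to be recorded).
#' @param cessation_offer_probability probability a recorded smoker has an
#'   offer of support recorded.
#' @param survey_sample_size per-district survey size (scalar or length
#'   `n_districts`).
#' @param mortality list: `coefficients` (named, log-IRR per unit),
#'   `dispersion` (NB2 alpha), `confounding_rho` (deprivation-smoking
#'   correlation), `target_mean_deaths`.
#' @param district_weights sampling weights for practice-to-district
#'   assignment (recycled/truncated to `n_districts`).
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_practices = 215,
                          n_districts = 16,
                          seed = 1,
                          list_size = list(meanlog = log(5500), sdlog = 0.6),
                          true_prevalence = list(shape1 = 5.7, shape2 = 24.3),
                          chronic_share = list(shape1 = 16.8, shape2 = 43.2),
                          chronic_smoking_offset = -0.0305,
                          recording = list(probability_general = 0.881,
                                           probability_chronic = 0.966,
                                           mar_log_odds_shift = 0),
                          cessation_offer_probability = 0.90,
                          survey_sample_size = 328,
                          mortality = list(
                            coefficients = c(smoking_prev = log(1.031),
                                             deprivation = log(1.017)),
                            dispersion = 0.1,
                            confounding_rho = 0.6,
                            target_mean_deaths = 8),
                          district_weights = DISTRICT_WEIGHTS) {
  cfg <- list(n_practices = n_practices, n_districts = n_districts,
              seed = seed, list_size = list_size,
              true_prevalence = true_prevalence,
              chronic_share = chronic_share,
              chronic_smoking_offset = chronic_smoking_offset,
              recording = recording,
              cessation_offer_probability = cessation_offer_probability,
              survey_sample_size = survey_sample_size,
              mortality = mortality,
              district_weights = rep_len(district_weights, n_districts))
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_practices >= 1, cfg$n_districts >= 1,
            cfg$n_practices >= cfg$n_districts)
  probs <- c(cfg$recording$probability_general,
             cfg$recording$probability_chronic,
             cfg$cessation_offer_probability)
  if (any(probs < 0 | probs > 1)) {
    stop_qof("probabilities must lie in [0, 1]", class = "qofprev_bad_config")
  }
  if (any(c(cfg$true_prevalence$shape1, cfg$true_prevalence$shape2,
            cfg$chronic_share$shape1, cfg$chronic_share$shape2) <= 0)) {
    stop_qof("Beta shapes must be positive", class = "qofprev_bad_config")
  }
  if (cfg$list_size$sdlog < 0) {
    stop_qof("list size sdlog must be non-negative",
             class = "qofprev_bad_config")
  }
  if (any(cfg$survey_sample_size < 1)) {
    stop_qof("survey sample sizes must be >= 1", class = "qofprev_bad_config")
  }
  if (cfg$mortality$dispersion < 0) {
    stop_qof("dispersion must be non-negative", class = "qofprev_bad_config")
  }
  structure(cfg, class = "cohort_config")
}

# deterministic synthetic postcode tokens (valid-looking, unique per index)
synthetic_postcode <- function(i) {
  sprintf("ZZ%d %d%s%s", (i - 1) %/% 100 + 1, (i - 1) %% 10,
          LETTERS[((i - 1) %/% 10) %% 26 + 1],
          LETTERS[(i - 1) %% 26 + 1])
}

draw_practice_truth <- function(cfg) {
  n <- cfg$n_practices
  n_elig <- pmax(100L, as.integer(round(
    stats::rlnorm(n, cfg$list_size$meanlog, cfg$list_size$sdlog))))
  p_gen <- stats::rbeta(n, cfg$true_prevalence$shape1,
                        cfg$true_prevalence$shape2)
  share <- stats::rbeta(n, cfg$chronic_share$shape1, cfg$chronic_share$shape2)
  district <- c(seq_len(cfg$n_districts),  # guarantee non-empty districts
                sample.int(cfg$n_districts, n - cfg$n_districts,
                           replace = TRUE, prob = cfg$district_weights))
  data.frame(
    practice_id = sprintf("P%03d", seq_len(n)),
    postcode = synthetic_postcode(seq_len(n)),
    district_code = sprintf("SYND%02d", district),
    n_eligible = n_elig,
    true_prev_general = p_gen,
    true_prev_chronic = pmin(pmax(p_gen + cfg$chronic_smoking_offset, 0.005),
                             0.95),
    chronic_share = share,
    stringsAsFactors = FALSE
  )
}

simulate_counts <- function(truth, cfg, year) {
  n <- nrow(truth)
  rg <- cfg$recording$probability_general
  rc <- cfg$recording$probability_chronic
  shift <- cfg$recording$mar_log_odds_shift %||% 0
  rg_s <- stats::plogis(stats::qlogis(min(max(rg, 1e-9), 1 - 1e-9)) + shift)
  rc_s <- stats::plogis(stats::qlogis(min(max(rc, 1e-9), 1 - 1e-9)) + shift)
  if (rg == 1) rg_s <- 1
  if (rc == 1) rc_s <- 1
  off <- cfg$cessation_offer_probability

  smokers <- stats::rbinom(n, truth$n_eligible, truth$true_prev_general)
  rec_s <- stats::rbinom(n, smokers, rg_s)
  rec_ns <- stats::rbinom(n, truth$n_eligible - smokers, rg)
  sm08_num <- stats::rbinom(n, rec_s, off)

  n_chr <- stats::rbinom(n, truth$n_eligible, truth$chronic_share)
  smokers_c <- stats::rbinom(n, n_chr, truth$true_prev_chronic)
  rec_cs <- stats::rbinom(n, smokers_c, rc_s)
  rec_cns <- stats::rbinom(n, n_chr - smokers_c, rc)
  sm06_num <- stats::rbinom(n, rec_cs, off)

  rec <- data.frame(
    practice_id = truth$practice_id,
    year = year,
    postcode = truth$postcode,
    sm07_num = rec_s + rec_ns,
    sm07_den = truth$n_eligible,
    sm08_num = sm08_num,
    sm08_den = rec_s,
    sm05_num = rec_cs + rec_cns,
    sm05_den = n_chr,
    sm06_num = sm06_num,
    sm06_den = rec_cs,
    stringsAsFactors = FALSE
  )
  list(records = new_qof_records(rec),
       realized = data.frame(practice_id = truth$practice_id,
                             smokers = smokers,
                             realized_prev_general = smokers / truth$n_eligible,
                             n_chronic = n_chr,
                             smokers_chronic = smokers_c,
                             realized_prev_chronic =
                               ifelse(n_chr > 0, smokers_c / n_chr, NA_real_)))
}

# roles without a published indicator code in a given year (e.g. general
# cessation before 2012/13) are blanked so records mirror what QOF printed
blank_unpublished_roles <- function(records, year) {
  map <- default_code_map()
  if (!(year %in% names(map))) return(records)
  codes <- map[[year]]
  for (role in names(codes)) {
    if (is.na(codes[[role]])) {
      for (cl in role_to_cols[[role]]) records[[cl]] <- NA_integer_
    }
  }
  records
}

district_truth <- function(practices) {
  num <- tapply(practices$smokers, practices$district_code, sum)
  den <- tapply(practices$n_eligible, practices$district_code, sum)
  data.frame(district_code = names(den),
             n_eligible = as.integer(den),
             true_prevalence = as.numeric(num / den),
             stringsAsFactors = FALSE)
}

#' Generate a one-year synthetic QOF registry with ground truth
#'
#' For each practice: draws an eligible population, true prevalence and
#' chronic share; realizes smoker counts binomially; records statuses with
#' the configured recording probabilities (smokers' recording odds shifted
#' by `mar_log_odds_shift`); and emits the four indicator
#' numerator/denominator pairs. All record invariants hold by
#' construction; output is a deterministic function of the config seed.
#'
#' @param config a `cohort_config`.
#' @param year financial-year label for the records.
#' @return list of class `qof_registry`: `records` (a `qof_records`),
#'   `truth` (list: `practices` with drawn parameters and realized counts,
#'   `districts` with the population-weighted realized district
#'   prevalence), `lookup` (postcode -> district data frame).
#' @export
generate_registry <- function(config, year = "2012/2013") {
  config <- validate_cohort_config(config)
  set.seed(substream(config$seed, 1))
  truth <- draw_practice_truth(config)
  sim <- simulate_counts(truth, config, year)
  practices <- cbind(truth, sim$realized[, -1, drop = FALSE])
  out <- list(
    records = sim$records,
    truth = list(practices = practices,
                 districts = district_truth(practices)),
    lookup = data.frame(postcode = truth$postcode,
                        district_code = truth$district_code,
                        stringsAsFactors = FALSE)
  )
  class(out) <- "qof_registry"
  out
}

#' Generate survey-style district prevalence estimates
#'
#' Binomial draws from each district's true prevalence at the given sample
#' sizes, emulating survey point estimates for local-authority districts.
#'
#' @param truth the `truth` element of a [generate_registry()] result (or
#'   any list with a `districts` data frame).
#' @param sample_sizes scalar or per-district vector of respondent counts.
#' @param seed random seed (defaults to a substream of nothing — supply
#'   one for reproducibility).
#' @return a `survey_estimates` data frame: `district_code`, `prevalence`,
#'   `sample_size`.
#' @export
generate_survey_estimates <- function(truth, sample_sizes = 328, seed = 1) {
  d <- truth$districts
  stopifnot(is.data.frame(d), nrow(d) >= 1)
  sizes <- rep_len(sample_sizes, nrow(d))
  if (any(sizes < 1)) {
    stop_qof("sample sizes must be >= 1", class = "qofprev_bad_config")
  }
  set.seed(substream(seed, 2))
  k <- stats::rbinom(nrow(d), sizes, d$true_prevalence)
  out <- data.frame(district_code = d$district_code,
                    prevalence = k / sizes,
                    sample_size = as.integer(sizes),
                    stringsAsFactors = FALSE)
  class(out) <- c("survey_estimates", "data.frame")
  out
}

#' Generate practice covariates and NB-distributed death counts
#'
#' Emulates the premature-CHD mortality design: practice covariates
#' (deprivation correlated with the smoking-prevalence estimate at
#' `confounding_rho`, the remaining service/population covariates
#' independent), a 3-year list-size exposure, and death counts drawn from
#' NB2 with log mean = log(exposure) + intercept + X beta. The intercept
#' is set so the expected death count matches `target_mean_deaths`.
#'
#' @param truth the `truth` element of a [generate_registry()] result;
#'   supplies practice ids and eligible populations.
#' @param coefficients named vector of per-unit log IRRs (names must be
#'   covariate names).
#' @param dispersion NB2 alpha (>= 0; 0 gives Poisson counts).
#' @param seed random seed.
#' @param confounding_rho deprivation-smoking correlation.
#' @param target_mean_deaths expected deaths per practice.
#' @return a `practice_covariates` data frame with `death_count`,
#'   `exposure`, and the full covariate set; true coefficients are kept in
#'   `attr(, "coefficients")`.
#' @export
generate_mortality <- function(truth,
                               coefficients = c(smoking_prev = log(1.031),
                                                deprivation = log(1.017)),
                               dispersion = 0.1, seed = 1,
                               confounding_rho = 0.6,
                               target_mean_deaths = 8) {
  if (dispersion < 0) {
    stop_qof("dispersion must be non-negative", class = "qofprev_bad_config")
  }
  p <- truth$practices
  n <- nrow(p)
  set.seed(substream(seed, 3))
  # deprivation and the smoking estimate share a latent factor
  z <- stats::rnorm(n)
  deprivation <- 25 + 8 * (confounding_rho * z +
                             sqrt(1 - confounding_rho^2) * stats::rnorm(n))
  smoking_prev <- pmax(2, 19 + 6 * z)
  cov <- data.frame(
    practice_id = p$practice_id,
    smoking_prev = smoking_prev,
    deprivation = deprivation,
    pct_white = pmin(100, pmax(40, stats::rnorm(n, 90, 8))),
    diabetes_prev = pmax(0.5, stats::rnorm(n, 4, 1)),
    pct_over65 = pmax(4, stats::rnorm(n, 16, 4)),
    pct_male = stats::rnorm(n, 49, 1.5),
    gps_per_1000 = pmax(0.2, stats::rnorm(n, 0.6, 0.15)),
    hypertension_detection = pmin(100, pmax(50, stats::rnorm(n, 82, 5))),
    smoking_advice = pmin(100, pmax(40, stats::rnorm(n, 88, 6))),
    cholesterol_achievement = pmin(100, pmax(30, stats::rnorm(n, 70, 8))),
    aspirin_achievement = pmin(100, pmax(40, stats::rnorm(n, 85, 6))),
    preferred_gp = pmin(100, pmax(30, stats::rnorm(n, 80, 10))),
    exposure = p$n_eligible * 3,
    stringsAsFactors = FALSE
  )
  unknown <- setdiff(names(coefficients), names(cov))
  if (length(unknown)) {
    stop_qof("coefficient name(s) not among covariates: ",
             paste(unknown, collapse = ", "), class = "qofprev_bad_config")
  }
  eta <- log(cov$exposure)
  for (nm in names(coefficients)) {
    eta <- eta + coefficients[[nm]] * cov[[nm]]
  }
  intercept <- log(target_mean_deaths) - mean(eta)
  mu <- exp(eta + intercept)
  cov$death_count <- if (dispersion == 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  cov <- cov[, c("practice_id", "death_count", "exposure",
                 setdiff(names(cov), c("practice_id", "death_count",
                                       "exposure")))]
  attr(cov, "coefficients") <- coefficients
  attr(cov, "intercept") <- intercept
  class(cov) <- c("practice_covariates", "data.frame")
  cov
}

#' Generate a multi-year registry with drifting truths
#'
#' Practice parameters (list size, chronic share, district) are fixed;
#' the logit of each practice's true prevalence evolves by a Gaussian
#' random walk with step `drift_sd` per year. Optionally injects missing
#' years (dropping one random year for each of `missing_practices`
#' practices, for complete-series filter tests) and flags
#' `restricted_practices` practice ids (returned in `restricted_ids`) to
#' be excluded by the caller.
#'
#' @param config a `cohort_config`.
#' @param n_years number of consecutive financial years (>= 2).
#' @param drift_sd per-year random-walk sd on the logit scale.
#' @param first_year starting financial year (default `"2006/2007"`).
#' @param missing_practices number of practices given a missing year.
#' @param restricted_practices number of practices flagged restricted.
#' @return list of class `qof_multiyear`: `records` (all years stacked),
#'   `truth_by_year` (per-year truth data frames), `years`,
#'   `restricted_ids`, `missing_report` (practice id, dropped year).
#' @export
generate_multiyear <- function(config, n_years = 7, drift_sd = 0.02,
                               first_year = "2006/2007",
                               missing_practices = 0,
                               restricted_practices = 0) {
  config <- validate_cohort_config(config)
  stopifnot(n_years >= 2, drift_sd >= 0)
  y0 <- as.integer(substr(first_year, 1, 4))
  years <- sprintf("%d/%d", y0 + seq_len(n_years) - 1, y0 + seq_len(n_years))
  set.seed(substream(config$seed, 4))
  base <- draw_practice_truth(config)
  logit_p <- stats::qlogis(base$true_prev_general)
  rec_list <- vector("list", n_years)
  truth_by_year <- vector("list", n_years)
  for (t in seq_len(n_years)) {
    if (t > 1) logit_p <- logit_p + stats::rnorm(nrow(base), 0, drift_sd)
    truth_t <- base
    truth_t$true_prev_general <- stats::plogis(logit_p)
    truth_t$true_prev_chronic <- pmin(pmax(
      truth_t$true_prev_general + config$chronic_smoking_offset, 0.005), 0.95)
    set.seed(substream(config$seed, 100 + t))
    sim <- simulate_counts(truth_t, config, years[t])
    rec_list[[t]] <- blank_unpublished_roles(sim$records, years[t])
    truth_by_year[[t]] <- cbind(truth_t, sim$realized[, -1, drop = FALSE])
  }
  records <- do.call(rbind, rec_list)
  class(records) <- c("qof_records", "data.frame")

  missing_report <- data.frame(practice_id = character(),
                               year = character(), stringsAsFactors = FALSE)
  if (missing_practices > 0) {
    stopifnot(missing_practices + restricted_practices <= config$n_practices)
    set.seed(substream(config$seed, 5))
    gap_ids <- sample(base$practice_id, missing_practices)
    gap_years <- sample(years, missing_practices, replace = TRUE)
    drop <- paste(records$practice_id, records$year) %in%
      paste(gap_ids, gap_years)
    records <- records[!drop, , drop = FALSE]
    rownames(records) <- NULL
    class(records) <- c("qof_records", "data.frame")
    missing_report <- data.frame(practice_id = gap_ids, year = gap_years,
                                 stringsAsFactors = FALSE)
  }
  restricted_ids <- character()
  if (restricted_practices > 0) {
    pool <- setdiff(base$practice_id, missing_report$practice_id)
    set.seed(substream(config$seed, 6))
    restricted_ids <- sample(pool, restricted_practices)
  }
  names(truth_by_year) <- years
  out <- list(records = records, truth_by_year = truth_by_year,
              years = years, restricted_ids = restricted_ids,
              missing_report = missing_report,
              lookup = data.frame(postcode = base$postcode,
                                  district_code = base$district_code,
                                  stringsAsFactors = FALSE))
  class(out) <- "qof_multiyear"
  out
}
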