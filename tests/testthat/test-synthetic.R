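test_that("config validation rejects illegal worlds before sampling", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(recording = list(probability_general = 1.2,
                                              probability_chronic = 0.9,
                                              mar_log_odds_shift = 0)),
               class = "qofprev_bad_config")
  expect_error(cohort_config(true_prevalence = list(shape1 = -1, shape2 = 2)),
               class = "qofprev_bad_config")
  expect_error(cohort_config(survey_sample_size = 0),
               class = "qofprev_bad_config")
  expect_error(cohort_config(mortality = list(coefficients = c(x = 0),
                                              dispersion = -0.5,
                                              confounding_rho = 0,
                                              target_mean_deaths = 5)),
               class = "qofprev_bad_config")
})

test_that("generation is deterministic in the seed, including CSV bytes", {
  cfg <- cohort_config(n_practices = 40, n_districts = 5, seed = 123)
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  expect_identical(r1, r2)
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_indicator_table(r1$records, p1)
  write_indicator_table(r2$records, p2)
  expect_identical(readLines(p1), readLines(p2))
  r3 <- generate_registry(cohort_config(n_practices = 40, n_districts = 5,
                                        seed = 124))
  expect_false(identical(r1$records, r3$records))
})

test_that("district ground truth equals the population-weighted mean of
           member practice truths", {
  reg <- generate_registry(cohort_config(n_practices = 80, n_districts = 6,
                                         seed = 2))
  p <- reg$truth$practices
  for (d in unique(p$district_code)) {
    sub <- p[p$district_code == d, ]
    expect_equal(
      reg$truth$districts$true_prevalence[
        reg$truth$districts$district_code == d],
      weighted.mean(sub$realized_prev_general, sub$n_eligible))
  }
})

test_that("survey estimates converge to district truth and their spread
           matches binomial theory", {
  reg <- generate_registry(cohort_config(n_practices = 60, n_districts = 4,
                                         seed = 6))
  big <- generate_survey_estimates(reg$truth, sample_sizes = 2e6, seed = 1)
  expect_equal(big$prevalence, reg$truth$districts$true_prevalence,
               tolerance = 2e-3)

  # pooled differences over replicate surveys at n = 150 per district
  diffs <- unlist(lapply(1:60, function(s) {
    sv <- generate_survey_estimates(reg$truth, sample_sizes = 150, seed = s)
    sv$prevalence - reg$truth$districts$true_prevalence
  }))
  theory <- sqrt(mean(reg$truth$districts$true_prevalence *
                        (1 - reg$truth$districts$true_prevalence)) / 150)
  expect_lt(abs(sd(diffs) / theory - 1), 0.15)
  expect_error(generate_survey_estimates(reg$truth, sample_sizes = 0),
               class = "qofprev_bad_config")
})

test_that("zero-dispersion mortality counts are Poisson-consistent and a
           null coefficient vector yields IRRs near 1", {
  reg <- generate_registry(cohort_config(n_practices = 215, seed = 14))
  dat <- generate_mortality(reg$truth, dispersion = 0, seed = 14)
  pois <- glm(death_count ~ smoking_prev + deprivation +
                offset(log(exposure)), data = dat, family = poisson())
  pearson_stat <- sum(residuals(pois, type = "pearson")^2) / pois$df.residual
  expect_lt(abs(pearson_stat - 1), 0.25)

  null_dat <- generate_mortality(reg$truth,
                                 coefficients = c(smoking_prev = 0,
                                                  deprivation = 0),
                                 dispersion = 0.05, seed = 15)
  fit <- fit_negative_binomial(null_dat, c("smoking_prev", "deprivation"))
  rows <- fit$table[fit$table$term != "(Intercept)", ]
  expect_true(all(rows$ci_lower < 1 & 1 < rows$ci_upper))
  expect_error(generate_mortality(reg$truth, dispersion = -1),
               class = "qofprev_bad_config")
  expect_error(generate_mortality(reg$truth, coefficients = c(bogus = 0.1)),
               class = "qofprev_bad_config")
})

test_that("multi-year generation: zero drift keeps truths fixed; early
           years blank the unpublished general cessation role", {
  cfg <- cohort_config(n_practices = 25, n_districts = 5, seed = 18)
  my <- generate_multiyear(cfg, n_years = 3, drift_sd = 0)
  t1 <- my$truth_by_year[[1]]$true_prev_general
  t3 <- my$truth_by_year[[3]]$true_prev_general
  expect_identical(t1, t3)
  early <- my$records[my$records$year == "2006/2007", ]
  expect_true(all(is.na(early$sm08_den)))
  y2012 <- generate_multiyear(cfg, n_years = 7)$records
  expect_true(all(!is.na(y2012$sm08_den[y2012$year == "2012/2013"])))
})

test_that("generated records satisfy the record invariants across random
           configs", {
  set.seed(77)
  for (i in 1:8) {
    cfg <- cohort_config(
      n_practices = sample(10:60, 1), n_districts = sample(2:6, 1),
      seed = sample.int(1e6, 1),
      recording = list(probability_general = runif(1, 0.5, 1),
                       probability_chronic = runif(1, 0.5, 1),
                       mar_log_odds_shift = runif(1, -1, 1)),
      cessation_offer_probability = runif(1, 0.5, 1))
    expect_silent(validate_qof_records(generate_registry(cfg)$records))
  }
})
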