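test_that("worked-example practices reproduce the printed cells at 1 dp", {
  rec <- table2_records()
  est <- derive_practice_estimates(rec)
  expect_equal(render_percent(est$prevalence_general),
               unname(TABLE2_PREV[est$practice_id]))
  expect_equal(render_percent(est$ua_status_general),
               unname(TABLE2_UA_STATUS[est$practice_id]))
  expect_equal(render_percent(est$ua_cessation_general),
               unname(TABLE2_UA_CESSATION[est$practice_id]))
  # chronic fields are absent exactly when the source indicators are
  expect_true(all(is.na(est$prevalence_chronic)))
  expect_true(all(is.na(est$chronic_share)))
})

test_that("scalar estimators: values, rounding and error conditions", {
  expect_equal(render_percent(estimate_prevalence(1129, 3721)), 30.3)
  expect_equal(render_percent(estimate_prevalence(2373, 7212)), 32.9)
  expect_equal(render_percent(estimate_prevalence(0, 1000)), 0)
  expect_equal(render_percent(underlying_achievement(1578, 1586)), 99.5)
  expect_equal(underlying_achievement(7, 7), 1)
  expect_error(estimate_prevalence(10, 0),
               class = "qofprev_undefined_estimate")
  expect_error(estimate_prevalence(11, 10), class = "qofprev_invariant")
  expect_error(underlying_achievement(5, 0),
               class = "qofprev_undefined_estimate")
  expect_error(estimate_prevalence(-1, 10), class = "qofprev_invalid_count")
})

test_that("list-based variant divides by the registered population", {
  expect_equal(render_percent(list_based_prevalence(1129, 4000)), 28.2)
  expect_equal(list_based_prevalence(0, 4000), 0)
  expect_equal(list_based_prevalence(1129, 3721),
               estimate_prevalence(1129, 3721))
  expect_error(list_based_prevalence(5, 0),
               class = "qofprev_undefined_estimate")
})

test_that("proportions are scale-equivariant in the counts", {
  set.seed(1)
  for (i in 1:20) {
    den <- sample(100:5000, 1)
    num <- sample(0:den, 1)
    k <- sample(2:9, 1)
    expect_identical(estimate_prevalence(num * k, den * k),
                     estimate_prevalence(num, den))
    expect_identical(underlying_achievement(num * k, den * k),
                     underlying_achievement(num, den))
  }
})

test_that("chronic fields collapse onto general ones when the registers
           coincide", {
  rec <- toy_records(5)
  rec$sm05_num <- rec$sm07_num
  rec$sm05_den <- rec$sm07_den
  rec$sm06_num <- rec$sm08_num
  rec$sm06_den <- rec$sm08_den
  est <- derive_practice_estimates(rec)
  expect_equal(est$prevalence_chronic, est$prevalence_general)
  expect_equal(est$chronic_share, rep(1, 5))
})

test_that("complete recording makes the estimate the realized smoker
           fraction exactly", {
  cfg <- cohort_config(n_practices = 40, n_districts = 4, seed = 5,
                       recording = list(probability_general = 1,
                                        probability_chronic = 1,
                                        mar_log_odds_shift = 0))
  reg <- generate_registry(cfg)
  est <- derive_practice_estimates(reg$records)
  expect_equal(est$prevalence_general,
               reg$truth$practices$realized_prev_general)
  expect_equal(est$ua_status_general, rep(1, 40))
})

test_that("MCAR recording at 0.85 scales the estimate by the recording
           rate; the recorded-ratio estimator stays unbiased", {
  # E[sm08_den / sm07_den] = r * p: the published-denominator estimator is
  # biased downward by (1 - r) * p under incomplete recording, however
  # random the recording; sm08_den / sm07_num is the MCAR-consistent form.
  r <- 0.85
  bias_published <- numeric(200)
  bias_scaled <- numeric(200)
  bias_recorded <- numeric(200)
  for (i in 1:200) {
    cfg <- cohort_config(n_practices = 50, n_districts = 5, seed = 1000 + i,
                         recording = list(probability_general = r,
                                          probability_chronic = r,
                                          mar_log_odds_shift = 0))
    reg <- generate_registry(cfg)
    rec <- reg$records
    truth <- reg$truth$practices$realized_prev_general
    est <- rec$sm08_den / rec$sm07_den
    bias_published[i] <- mean(est - truth)
    bias_scaled[i] <- mean(est - r * truth)
    bias_recorded[i] <- mean(
      prevalence_among_recorded(rec$sm08_den, rec$sm07_num) - truth)
  }
  expect_lt(mean(bias_published), -0.01)          # systematic underestimate
  expect_lt(abs(mean(bias_scaled)), 0.005)        # exactly r * p on average
  expect_lt(abs(mean(bias_recorded)), 0.005)      # MCAR-consistent, < 0.5 pp
})

test_that("when smokers are less likely to be recorded the estimate falls
           further below the truth", {
  biases <- sapply(c(0, -1), function(shift) {
    b <- numeric(100)
    for (i in 1:100) {
      cfg <- cohort_config(n_practices = 50, n_districts = 5, seed = 2000 + i,
                           recording = list(probability_general = 0.9,
                                            probability_chronic = 0.9,
                                            mar_log_odds_shift = shift))
      reg <- generate_registry(cfg)
      b[i] <- mean(reg$records$sm08_den / reg$records$sm07_den -
                     reg$truth$practices$realized_prev_general)
    }
    mean(b)
  })
  expect_lt(biases[2], biases[1])  # differential under-recording of smokers
  expect_lt(biases[2], -0.02)      # well below truth
})

test_that("prevalence_matrix aligns practices and errors on gaps", {
  my <- generate_multiyear(cohort_config(n_practices = 20, n_districts = 4,
                                         seed = 8), n_years = 3)
  est <- derive_practice_estimates(my$records)
  m <- prevalence_matrix(est)
  expect_equal(dim(m), c(20, 3))
  est2 <- est[-1, ]
  expect_error(prevalence_matrix(est2), class = "qofprev_misaligned")
})
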