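test_that("long-format reader populates one record per practice-year", {
  rec <- read_indicator_table(table2_long_path())
  expect_s3_class(rec, "qof_records")
  expect_equal(nrow(rec), 5)
  a <- rec[rec$practice_id == "A", ]
  expect_equal(a$sm07_num, 3450)
  expect_equal(a$sm07_den, 3721)
  expect_equal(a$sm08_num, 1024)
  expect_equal(a$sm08_den, 1129)
  expect_true(all(is.na(rec$sm05_den)))  # chronic roles absent, not zero
})

test_that("reader edge cases: empty file, unknown codes, malformed values,
           duplicates, invariant violations", {
  hdr <- "practice_id,year,indicator,numerator,denominator\n"
  empty <- tempfile(fileext = ".csv")
  writeLines(sub("\n$", "", hdr), empty)
  expect_equal(nrow(read_indicator_table(empty)), 0)

  unk <- tempfile(fileext = ".csv")
  writeLines(c("practice_id,year,indicator,numerator,denominator",
               "A,2012/2013,SM07,10,20",
               "A,2012/2013,CHD08,5,9"), unk)
  expect_message(
    rec <- read_indicator_table(unk, quiet = FALSE),
    "unknown")
  expect_equal(nrow(rec), 1)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("practice_id,year,indicator,numerator,denominator",
               "A,2012/2013,SM07,ten,20"), bad)
  expect_error(read_indicator_table(bad), class = "qofprev_bad_value")
  expect_error(read_indicator_table(bad), "A")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("practice_id,year,indicator,numerator,denominator",
               "A,2012/2013,SM07,10,20",
               "A,2012/2013,SM07,10,20"), dup)
  expect_error(read_indicator_table(dup), class = "qofprev_duplicate_rows")

  # recorded smokers exceed recorded statuses for practice Z
  inv <- tempfile(fileext = ".csv")
  writeLines(c("practice_id,year,indicator,numerator,denominator",
               "Z,2012/2013,SM07,100,200",
               "Z,2012/2013,SM08,90,150"), inv)
  err <- expect_error(read_indicator_table(inv), class = "qofprev_invariant")
  expect_match(conditionMessage(err), "Z")
})

test_that("long CSV round-trip is the identity", {
  rec <- toy_records(8)
  path <- tempfile(fileext = ".csv")
  write_indicator_table(rec, path)
  back <- read_indicator_table(path)
  ord <- order(back$practice_id)
  expect_equal(as.data.frame(back[ord, ]), as.data.frame(rec),
               ignore_attr = TRUE)
})

test_that("every record surviving validation satisfies all invariants", {
  for (seed in 1:5) {
    reg <- generate_registry(cohort_config(n_practices = 30, n_districts = 4,
                                           seed = seed))
    r <- reg$records
    expect_silent(validate_qof_records(r))
    expect_true(all(r$sm07_num <= r$sm07_den))
    expect_true(all(r$sm08_num <= r$sm08_den))
    expect_true(all(r$sm08_den <= r$sm07_num))
    expect_true(all(r$sm06_den <= r$sm05_num))
    expect_true(all(r$sm05_den <= r$sm07_den))
  }
})

test_that("postcode normalization and lookup reader", {
  expect_equal(normalize_postcode("le1 5ww"), "LE1 5WW")
  expect_equal(normalize_postcode("LE15WW"), "LE1 5WW")
  expect_equal(normalize_postcode(" b1  1bb "), "B1 1BB")

  path <- tempfile(fileext = ".csv")
  writeLines(c("postcode,district", "le1 5ww,E06000016", "LE2 7XX,E06000016"),
             path)
  lk <- read_postcode_lookup(path)
  expect_equal(unname(lk["LE1 5WW"]), "E06000016")

  writeLines("postcode,district", path)
  expect_length(read_postcode_lookup(path), 0)

  writeLines(c("postcode,district", "LE1 5WW,E06000016", "le15ww,E07000131"),
             path)
  expect_error(read_postcode_lookup(path),
               class = "qofprev_duplicate_postcode")

  # generated lookup: 215 keys across 16 districts
  reg <- generate_registry(cohort_config(seed = 3))
  path2 <- tempfile(fileext = ".csv")
  write.csv(reg$lookup, path2, row.names = FALSE)
  lk2 <- read_postcode_lookup(path2)
  expect_length(lk2, 215)
  expect_equal(length(unique(lk2)), 16)
})

test_that("complete-series filter retains only fully observed practices and
           is idempotent", {
  yrs <- c("2012/2013", "2013/2014")
  rec <- rbind(toy_records(3, year = yrs[1]), toy_records(3, year = yrs[2]))
  rec <- rec[!(rec$practice_id == "T03" & rec$year == yrs[2]), ]
  class(rec) <- c("qof_records", "data.frame")
  kept <- filter_complete_series(rec, yrs)
  expect_setequal(unique(kept$practice_id), c("T01", "T02"))
  excl <- attr(kept, "exclusions")
  expect_equal(excl$practice_id, "T03")
  expect_equal(excl$missing_years, yrs[2])
  again <- filter_complete_series(kept, yrs)
  expect_equal(as.data.frame(again), as.data.frame(kept), ignore_attr = TRUE)

  # all complete -> unchanged
  full <- rbind(toy_records(3, year = yrs[1]), toy_records(3, year = yrs[2]))
  class(full) <- c("qof_records", "data.frame")
  kept_full <- filter_complete_series(full, yrs)
  expect_equal(nrow(kept_full), nrow(full))
})

test_that("cohort of 230 with 14 gap practices and 1 restricted retains 215", {
  my <- generate_multiyear(cohort_config(n_practices = 230, seed = 11),
                           n_years = 7, missing_practices = 14,
                           restricted_practices = 1)
  expect_equal(nrow(my$missing_report), 14)
  expect_length(my$restricted_ids, 1)
  kept <- filter_complete_series(my$records, my$years,
                                 exclude = my$restricted_ids)
  expect_equal(length(unique(kept$practice_id)), 215)
  excl <- attr(kept, "exclusions")
  expect_equal(sum(excl$reason == "incomplete_series"), 14)
  expect_equal(sum(excl$reason == "excluded_by_caller"), 1)
})

test_that("code maps validate and read from YAML", {
  expect_s3_class(default_code_map(), "indicator_code_map")
  yml <- system.file("extdata", "indicator_codes.yaml", package = "qofprev")
  m <- read_code_map(yml)
  expect_equal(unname(m[["2012/2013"]][["status_general"]]), "SM07")
  expect_true(is.na(m[["2006/2007"]][["cessation_general"]]))
  expect_error(
    qofprev:::validate_code_map(list("2012/2013" = c(
      status_general = "SM07", cessation_general = "SM07",
      status_chronic = "SM05", cessation_chronic = "SM06"))),
    class = "qofprev_bad_code_map")
})
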