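# Shared fixtures, built in code.

options(qofprev.quiet = TRUE)

# the five worked-example practices (2012/13 general-population indicators)
table2_records <- function() {
  read_indicator_wide(write_wide_fixture())
}

write_wide_fixture <- function() {
  df <- data.frame(
    practice_id = c("A", "B", "C", "D", "E"),
    year = "2012/2013",
    postcode = c("AA1 1AA", "AA2 2BB", "AA3 3CC", "AA4 4DD", "AA5 5EE"),
    sm07_num = c(3450, 1319, 6276, 31948, 6504),
    sm07_den = c(3721, 1497, 7033, 37654, 7212),
    sm08_num = c(1024, 325, 1578, 8439, 2165),
    sm08_den = c(1129, 401, 1586, 10931, 2373)
  )
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

table2_long_path <- function() {
  system.file("extdata", "qof_example_2012.csv", package = "qofprev")
}

# printed Table-style reference values (1-dp percentages)
TABLE2_PREV <- c(A = 30.3, B = 26.8, C = 22.6, D = 29.0, E = 32.9)
TABLE2_UA_STATUS <- c(A = 92.7, B = 88.1, C = 89.2, D = 84.8, E = 90.2)
TABLE2_UA_CESSATION <- c(A = 90.7, B = 81.0, C = 99.5, D = 77.2, E = 91.2)

# small fully-populated record set (chronic + general), valid by construction
toy_records <- function(n = 6, year = "2012/2013", seed = 99) {
  set.seed(seed)
  elig <- sample(2000:9000, n)
  smok <- rbinom(n, elig, 0.2)
  rec <- rbinom(n, elig - smok, 0.9) + smok  # all smokers recorded
  chr <- rbinom(n, elig, 0.3)
  chr_s <- rbinom(n, chr, 0.17)
  df <- data.frame(
    practice_id = sprintf("T%02d", seq_len(n)), year = year,
    postcode = sprintf("TT%d 1AA", seq_len(n)),
    sm07_num = rec, sm07_den = elig,
    sm08_num = rbinom(n, smok, 0.9), sm08_den = smok,
    sm05_num = chr, sm05_den = chr,
    sm06_num = rbinom(n, chr_s, 0.9), sm06_den = chr_s
  )
  qofprev:::new_qof_records(df)
}
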