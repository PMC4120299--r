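# Reading, validating and filtering QOF-style indicator extracts.
#
# The canonical on-disk dialect is the "long" format published for QOF
# achievement data: one row per practice x indicator with NUMERATOR and
# DENOMINATOR columns. Internally one row per practice-year holds the four
# indicator roles under the 2012/13 code names:
#   sm07_* : smoking-status recording, general population aged 15+
#   sm08_* : cessation support offered to recorded current smokers, general
#   sm05_* : smoking-status recording, chronic-condition register
#   sm06_* : cessation support offered, chronic-condition register
# Earlier years map their own codes (Records 22/23, SM01-SM04, SMOK00x) onto
# the same roles through an IndicatorCodeMap; roles absent in a year are NA.

ROLE_COLS <- c("sm07_num", "sm07_den", "sm08_num", "sm08_den",
               "sm05_num", "sm05_den", "sm06_num", "sm06_den")
ROLE_NAMES <- c("status_general", "cessation_general",
                "status_chronic", "cessation_chronic")
role_to_cols <- list(
  status_general    = c("sm07_num", "sm07_den"),
  cessation_general = c("sm08_num", "sm08_den"),
  status_chronic    = c("sm05_num", "sm05_den"),
  cessation_chronic = c("sm06_num", "sm06_den")
)

#' Default indicator code map (2006/2007 to 2014/2015)
#'
#' Maps each financial year to the indicator codes filling the four roles:
#' general/chronic smoking-status recording and cessation-support offer.
#' General-population cessation codes (hence a general prevalence estimate)
#' exist only from 2012/13; the general status-recording role in earlier
#' years is served by the practice-records indicators 22/23. The
#' general status role is retired in 2014/15.
#'
#' @return a named list (year -> named character vector of roles, NA for
#'   roles unavailable that year) of class `indicator_code_map`.
#' @export
default_code_map <- function() {
  m <- list(
    "2006/2007" = c(status_general = "RECORDS22", cessation_general = NA,
                    status_chronic = "SM01", cessation_chronic = "SM02"),
    "2007/2008" = c(status_general = "RECORDS22", cessation_general = NA,
                    status_chronic = "SM01", cessation_chronic = "SM02"),
    "2008/2009" = c(status_general = "RECORDS23", cessation_general = NA,
                    status_chronic = "SM03", cessation_chronic = "SM04"),
    "2009/2010" = c(status_general = "RECORDS23", cessation_general = NA,
                    status_chronic = "SM03", cessation_chronic = "SM04"),
    "2010/2011" = c(status_general = "RECORDS23", cessation_general = NA,
                    status_chronic = "SM03", cessation_chronic = "SM04"),
    "2011/2012" = c(status_general = "RECORDS23", cessation_general = NA,
                    status_chronic = "SM03", cessation_chronic = "SM04"),
    "2012/2013" = c(status_general = "SM07", cessation_general = "SM08",
                    status_chronic = "SM05", cessation_chronic = "SM06"),
    "2013/2014" = c(status_general = "SMOK001", cessation_general = "SMOK004",
                    status_chronic = "SMOK002", cessation_chronic = "SMOK005"),
    "2014/2015" = c(status_general = NA, cessation_general = "SMOK004",
                    status_chronic = "SMOK002", cessation_chronic = "SMOK005")
  )
  validate_code_map(m)
}

#' Read an indicator code map from a YAML file
#'
#' The file maps year labels to the four role names (see
#' [default_code_map()]); missing roles may be omitted or `null`.
#'
#' @param path YAML file path.
#' @return an `indicator_code_map`.
#' @export
read_code_map <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  m <- lapply(raw, function(entry) {
    v <- stats::setNames(rep(NA_character_, 4), ROLE_NAMES)
    for (r in intersect(names(entry), ROLE_NAMES)) {
      if (!is.null(entry[[r]])) v[[r]] <- as.character(entry[[r]])
    }
    v
  })
  validate_code_map(m)
}

validate_code_map <- function(m) {
  stopifnot(is.list(m), length(m) >= 1, !is.null(names(m)))
  for (yr in names(m)) {
    v <- m[[yr]]
    if (!all(ROLE_NAMES %in% names(v))) {
      stop_qof("code map for year ", yr, " must name the four roles",
               class = "qofprev_bad_code_map")
    }
    codes <- v[!is.na(v)]
    if (anyDuplicated(codes)) {
      stop_qof("code map for year ", yr, " assigns one code to two roles",
               class = "qofprev_bad_code_map")
    }
  }
  structure(m, class = "indicator_code_map")
}

new_qof_records <- function(df) {
  base <- data.frame(practice_id = character(), year = character(),
                     postcode = character(), stringsAsFactors = FALSE)
  for (cl in ROLE_COLS) base[[cl]] <- integer()
  if (!missing(df) && nrow(df) > 0) {
    for (cl in setdiff(names(base), names(df))) df[[cl]] <- NA
    df <- df[, names(base)]
    for (cl in ROLE_COLS) df[[cl]] <- as.integer(df[[cl]])
    base <- df
  }
  rownames(base) <- NULL
  class(base) <- c("qof_records", "data.frame")
  base
}

#' Validate a collection of practice indicator records
#'
#' Enforces the record invariants: counts are non-negative integers,
#' numerators never exceed denominators, recorded current smokers
#' (`sm08_den`) are a subset of patients with status recorded (`sm07_num`),
#' recorded chronic smokers (`sm06_den`) a subset of chronic patients with
#' status recorded (`sm05_num`), and the chronic register (`sm05_den`) a
#' subset of the eligible population (`sm07_den`). Checks apply wherever
#' both fields of a comparison are present; absent roles stay `NA`.
#'
#' @param records a `qof_records` data frame.
#' @return the records, invisibly, if valid; otherwise an error naming the
#'   offending practices and fields.
#' @export
validate_qof_records <- function(records) {
  stopifnot(inherits(records, "data.frame"))
  for (cl in ROLE_COLS) check_count(records[[cl]], cl)
  pair_le <- function(a, b, label) {
    bad <- !is.na(records[[a]]) & !is.na(records[[b]]) &
      records[[a]] > records[[b]]
    if (any(bad)) {
      stop_qof("invariant ", label, " violated for practice(s): ",
               paste(unique(records$practice_id[bad]), collapse = ", "),
               class = "qofprev_invariant")
    }
  }
  pair_le("sm07_num", "sm07_den", "sm07_num <= sm07_den")
  pair_le("sm08_num", "sm08_den", "sm08_num <= sm08_den")
  pair_le("sm05_num", "sm05_den", "sm05_num <= sm05_den")
  pair_le("sm06_num", "sm06_den", "sm06_num <= sm06_den")
  pair_le("sm08_den", "sm07_num", "sm08_den <= sm07_num")
  pair_le("sm06_den", "sm05_num", "sm06_den <= sm05_num")
  pair_le("sm05_den", "sm07_den", "sm05_den <= sm07_den")
  invisible(records)
}

#' Read a long-format QOF indicator extract
#'
#' Expects a UTF-8 CSV with header columns `practice_id`, `year`,
#' `indicator`, `numerator`, `denominator` and optionally `postcode`
#' (case-insensitive; `practice`/`code` aliases accepted). Rows whose
#' indicator code is not in the code map for their year are ignored with a
#' logged count; duplicate (practice, year, indicator) rows are an error.
#'
#' @param path CSV file path.
#' @param code_map an `indicator_code_map`; default [default_code_map()].
#' @param quiet suppress INFO logging.
#' @return a validated `qof_records` data frame, one row per practice-year.
#' @export
read_indicator_table <- function(path, code_map = default_code_map(),
                                 quiet = getOption("qofprev.quiet", FALSE)) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  names(raw) <- tolower(names(raw))
  alias <- c(practice = "practice_id", code = "indicator")
  for (a in names(alias)) {
    if (a %in% names(raw) && !(alias[[a]] %in% names(raw)))
      names(raw)[names(raw) == a] <- alias[[a]]
  }
  need <- c("practice_id", "year", "indicator", "numerator", "denominator")
  if (!all(need %in% names(raw))) {
    stop_qof("missing required column(s): ",
             paste(setdiff(need, names(raw)), collapse = ", "),
             class = "qofprev_bad_file")
  }
  if (nrow(raw) == 0) return(new_qof_records())
  if (!("postcode" %in% names(raw))) raw$postcode <- NA_character_

  for (cl in c("numerator", "denominator")) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- is.na(v) & !(is.na(raw[[cl]]) | raw[[cl]] == "")
    if (any(bad)) {
      stop_qof("malformed numeric ", cl, " for practice(s): ",
               paste(unique(raw$practice_id[bad]), collapse = ", "),
               class = "qofprev_bad_value")
    }
    raw[[cl]] <- v
  }
  key <- paste(raw$practice_id, raw$year, raw$indicator, sep = "\r")
  if (anyDuplicated(key)) {
    stop_qof("duplicate (practice, year, indicator) rows: ",
             paste(utils::head(unique(gsub("\r", "/", key[duplicated(key)])), 5),
                   collapse = "; "),
             class = "qofprev_duplicate_rows")
  }

  # role for each row via the year's code map
  raw$role <- NA_character_
  known_year <- raw$year %in% names(code_map)
  for (yr in unique(raw$year[known_year])) {
    codes <- code_map[[yr]]
    sel <- raw$year == yr
    idx <- match(raw$indicator[sel], codes)
    raw$role[sel] <- names(codes)[idx]
  }
  n_drop <- sum(is.na(raw$role))
  if (n_drop > 0) {
    qp_inform("ignoring ", n_drop, " row(s) with indicator codes unknown ",
              "to the code map", quiet = quiet)
  }
  raw <- raw[!is.na(raw$role), , drop = FALSE]
  if (nrow(raw) == 0) return(new_qof_records())

  keys <- unique(raw[, c("practice_id", "year")])
  keys <- keys[order(keys$practice_id, keys$year), , drop = FALSE]
  out <- keys
  out$postcode <- NA_character_
  for (cl in ROLE_COLS) out[[cl]] <- NA_integer_
  rkey <- paste(raw$practice_id, raw$year, sep = "\r")
  okey <- paste(out$practice_id, out$year, sep = "\r")
  for (i in seq_len(nrow(raw))) {
    j <- match(rkey[i], okey)
    cols <- role_to_cols[[raw$role[i]]]
    out[[cols[1]]][j] <- as.integer(raw$numerator[i])
    out[[cols[2]]][j] <- as.integer(raw$denominator[i])
    pc <- raw$postcode[i]
    if (!is.na(pc) && nzchar(pc)) out$postcode[j] <- normalize_postcode(pc)
  }
  out <- new_qof_records(out)
  validate_qof_records(out)
  qp_inform("read ", nrow(raw), " indicator row(s) -> ", nrow(out),
            " practice-year record(s) from ", path, quiet = quiet)
  out
}

#' Read a wide-format indicator extract (convenience)
#'
#' One row per practice-year with the role columns already named
#' `sm07_num`, ..., `sm06_den` (plus `practice_id`, `year`, optional
#' `postcode`).
#'
#' @param path CSV file path.
#' @return a validated `qof_records` data frame.
#' @export
read_indicator_wide <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  stopifnot(all(c("practice_id", "year") %in% names(raw)))
  if (!("postcode" %in% names(raw))) raw$postcode <- NA_character_
  if (anyDuplicated(paste(raw$practice_id, raw$year))) {
    stop_qof("duplicate practice-year rows", class = "qofprev_duplicate_rows")
  }
  if (!is.null(raw$postcode)) {
    has <- !is.na(raw$postcode) & nzchar(raw$postcode)
    raw$postcode[has] <- normalize_postcode(raw$postcode[has])
  }
  out <- new_qof_records(raw)
  validate_qof_records(out)
  out
}

#' Write records in the canonical long CSV dialect
#'
#' Inverse of [read_indicator_table()]: writing then re-reading with the
#' same code map yields identical records.
#'
#' @param records a `qof_records` data frame.
#' @param path output CSV path.
#' @param code_map code map naming each role's indicator code per year.
#' @return `path`, invisibly.
#' @export
write_indicator_table <- function(records, path,
                                  code_map = default_code_map()) {
  rows <- list()
  for (i in seq_len(nrow(records))) {
    yr <- records$year[i]
    codes <- if (yr %in% names(code_map)) code_map[[yr]] else
      stop_qof("year ", yr, " not in code map", class = "qofprev_bad_code_map")
    for (role in ROLE_NAMES) {
      cols <- role_to_cols[[role]]
      num <- records[[cols[1]]][i]
      den <- records[[cols[2]]][i]
      if (is.na(num) && is.na(den)) next
      if (is.na(codes[[role]])) {
        stop_qof("role ", role, " populated but has no code in year ", yr,
                 class = "qofprev_bad_code_map")
      }
      rows[[length(rows) + 1]] <- data.frame(
        practice_id = records$practice_id[i], year = yr,
        postcode = records$postcode[i], indicator = codes[[role]],
        numerator = num, denominator = den, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(practice_id = character(), year = character(),
               postcode = character(), indicator = character(),
               numerator = integer(), denominator = integer())
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Retain practices with a complete indicator series
#'
#' Keeps only practices that have, for every required year, a record with
#' non-missing chronic status and cessation fields (the indicators
#' published for the whole study window). An exclusion report — practice id
#' and the years it is missing — is attached as attribute `"exclusions"`.
#' Practices named in `exclude` (e.g. a restricted-list practice, or one
#' flagged for a suspected data error) are removed regardless of
#' completeness, with reason `"excluded_by_caller"`. Idempotent.
#'
#' @param records a `qof_records` data frame.
#' @param required_years character vector of year labels, non-empty.
#' @param exclude practice ids to drop unconditionally.
#' @param quiet suppress INFO logging.
#' @return the retained records (`qof_records`), with the exclusion report
#'   in `attr(, "exclusions")`.
#' @export
filter_complete_series <- function(records, required_years, exclude = NULL,
                                   quiet = getOption("qofprev.quiet", FALSE)) {
  stopifnot(length(required_years) >= 1)
  has_chronic <- !is.na(records$sm05_num) & !is.na(records$sm05_den) &
    !is.na(records$sm06_num) & !is.na(records$sm06_den)
  ids <- unique(records$practice_id)
  missing_by_id <- lapply(ids, function(id) {
    ok_years <- records$year[records$practice_id == id & has_chronic]
    setdiff(required_years, ok_years)
  })
  names(missing_by_id) <- ids
  excl <- data.frame(practice_id = character(), reason = character(),
                     missing_years = character(), stringsAsFactors = FALSE)
  drop <- character()
  for (id in ids) {
    miss <- missing_by_id[[id]]
    if (id %in% exclude) {
      excl <- rbind(excl, data.frame(practice_id = id,
                                     reason = "excluded_by_caller",
                                     missing_years = ""))
      drop <- c(drop, id)
    } else if (length(miss) > 0) {
      excl <- rbind(excl, data.frame(practice_id = id,
                                     reason = "incomplete_series",
                                     missing_years = paste(miss, collapse = ";")))
      drop <- c(drop, id)
    }
  }
  keep <- records[!(records$practice_id %in% drop) &
                    records$year %in% required_years, , drop = FALSE]
  rownames(keep) <- NULL
  class(keep) <- c("qof_records", "data.frame")
  attr(keep, "exclusions") <- excl
  qp_inform("complete-series filter: retained ",
            length(unique(keep$practice_id)), " of ", length(ids),
            " practice(s); excluded ", nrow(excl), quiet = quiet)
  keep
}

#' Normalize UK-style postcodes
#'
#' Uppercases and collapses internal whitespace to a single space placed
#' before the final three characters (NSPD extracts vary in spacing).
#'
#' @param x character vector of postcodes.
#' @return normalized character vector.
#' @examples
#' normalize_postcode("le1 5ww") # "LE1 5WW"
#' @export
normalize_postcode <- function(x) {
  squashed <- gsub("[[:space:]]+", "", toupper(trimws(x)))
  n <- nchar(squashed)
  ifelse(n > 3,
         paste(substr(squashed, 1, n - 3), substr(squashed, n - 2, n)),
         squashed)
}

#' Read a postcode-to-district lookup table
#'
#' Two-column CSV (postcode, district code), the minimal NSPD-style
#' dialect. Keys are normalized with [normalize_postcode()].
#'
#' @param path CSV file path.
#' @return a named character vector mapping postcode to district code.
#' @export
read_postcode_lookup <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0) return(stats::setNames(character(), character()))
  if (ncol(raw) < 2) {
    stop_qof("postcode lookup needs two columns", class = "qofprev_bad_file")
  }
  pc <- normalize_postcode(raw[[1]])
  dist <- raw[[2]]
  dup <- duplicated(pc)
  if (any(dup)) {
    conflict <- vapply(unique(pc[dup]), function(k) {
      length(unique(dist[pc == k])) > 1
    }, logical(1))
    if (any(conflict)) {
      stop_qof("conflicting districts for postcode(s): ",
               paste(names(conflict)[conflict], collapse = ", "),
               class = "qofprev_duplicate_postcode")
    }
    pc <- pc[!dup]
    dist <- dist[!dup]
  }
  stats::setNames(dist, pc)
}

#' Read area-level survey prevalence estimates
#'
#' CSV with columns `district_code`, `prevalence` (proportion in \[0,1\])
#' and `sample_size` (positive integer).
#'
#' @param path CSV file path.
#' @return a data frame of class `survey_estimates`.
#' @export
read_survey_estimates <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("district_code", "prevalence", "sample_size")
  stopifnot(all(need %in% names(df)))
  if (any(df$prevalence < 0 | df$prevalence > 1, na.rm = TRUE)) {
    stop_qof("survey prevalence must be a proportion in [0,1]",
             class = "qofprev_bad_value")
  }
  check_count(df$sample_size, "sample_size")
  if (any(df$sample_size < 1)) {
    stop_qof("survey sample_size must be >= 1", class = "qofprev_bad_value")
  }
  class(df) <- c("survey_estimates", "data.frame")
  df
}

#' Read a practice covariate/mortality table
#'
#' CSV with columns `practice_id`, `death_count`, `exposure` and any
#' numeric covariates used by [fit_negative_binomial()].
#'
#' @param path CSV file path.
#' @return a data frame of class `practice_covariates`.
#' @export
read_covariate_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("practice_id", "death_count", "exposure") %in% names(df)))
  check_count(df$death_count, "death_count")
  if (any(df$exposure <= 0)) {
    stop_qof("exposure must be positive", class = "qofprev_bad_value")
  }
  class(df) <- c("practice_covariates", "data.frame")
  df
}
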