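# End-to-end pipeline: simulate -> estimate -> aggregate -> agree -> model.
# Stages communicate only through CSV files so each can be re-run or
# audited standalone; the run log records row counts and exclusions.

#' Run the full pipeline
#'
#' Executes the stages in order and writes per-stage CSVs plus a summary
#' report to `config$outdir`. The configuration is a list (or the path of
#' a YAML file holding one) with entries:
#' \describe{
#'   \item{outdir}{output directory (created if absent).}
#'   \item{seed}{global seed; with `simulate = TRUE` drives the generator.}
#'   \item{simulate}{logical; if `TRUE` inputs are generated from
#'     `cohort` (arguments for [cohort_config()]).}
#'   \item{indicator_file, lookup_file, survey_file, covariate_file}{input
#'     CSVs when `simulate = FALSE`; `survey_file` and `covariate_file`
#'     are optional — their stages are skipped with a logged notice.}
#'   \item{year}{financial year to estimate (default `"2012/2013"`).}
#'   \item{aggregation}{`"pooled"`, `"mean"` or `"weighted-mean"`.}
#'   \item{outlier_threshold}{calibration outlier cutoff (default 3).}
#'   \item{model}{list: `covariates`, `add` (covariate for the
#'     with/without comparison), `offset`.}
#' }
#'
#' @param config list or YAML file path.
#' @param quiet suppress INFO logging.
#' @return invisibly, a list with the per-stage results (`estimates`,
#'   `districts`, `agreement`, `calibration`, `model`, `log`).
#' @export
run_pipeline <- function(config, quiet = getOption("qofprev.quiet", FALSE)) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$outdir))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  year <- config$year %||% "2012/2013"
  log <- list(seed = seed, stages = character())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_qof("stage '", name, "' failed: ", conditionMessage(e),
               class = "qofprev_stage_error")
    })
  }

  # --- inputs ---------------------------------------------------------
  survey <- NULL
  covars <- NULL
  if (isTRUE(config$simulate)) {
    cohort_args <- config$cohort %||% list()
    cohort_args$seed <- seed
    cfg <- run_stage("simulate", do.call(cohort_config, cohort_args))
    reg <- run_stage("simulate", generate_registry(cfg, year = year))
    records <- reg$records
    lookup <- stats::setNames(reg$lookup$district_code, reg$lookup$postcode)
    survey <- generate_survey_estimates(reg$truth,
                                        cfg$survey_sample_size, seed = seed)
    covars <- generate_mortality(reg$truth,
                                 coefficients = cfg$mortality$coefficients,
                                 dispersion = cfg$mortality$dispersion,
                                 seed = seed,
                                 confounding_rho = cfg$mortality$confounding_rho,
                                 target_mean_deaths = cfg$mortality$target_mean_deaths)
    write_indicator_table(records, file.path(outdir, "registry.csv"))
    utils::write.csv(reg$lookup, file.path(outdir, "lookup.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(survey), file.path(outdir, "survey.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(covars),
                     file.path(outdir, "covariates.csv"), row.names = FALSE)
    utils::write.csv(reg$truth$practices,
                     file.path(outdir, "ground_truth.csv"), row.names = FALSE)
    log$stages <- c(log$stages, "simulate")
  } else {
    records <- run_stage("read",
                         read_indicator_table(config$indicator_file,
                                              quiet = quiet))
    lookup <- if (!is.null(config$lookup_file))
      run_stage("read", read_postcode_lookup(config$lookup_file)) else NULL
    if (!is.null(config$survey_file))
      survey <- run_stage("read", read_survey_estimates(config$survey_file))
    if (!is.null(config$covariate_file))
      covars <- run_stage("read", read_covariate_table(config$covariate_file))
    log$stages <- c(log$stages, "read")
  }

  # --- estimate -------------------------------------------------------
  est <- run_stage("estimate", derive_practice_estimates(
    records[records$year == year, , drop = FALSE]))
  utils::write.csv(as.data.frame(est), file.path(outdir, "estimates.csv"),
                   row.names = FALSE)
  log$stages <- c(log$stages, "estimate")
  log$n_practices <- length(unique(est$practice_id))
  qp_inform("estimate stage: ", nrow(est), " practice estimate(s)",
            quiet = quiet)

  # --- aggregate ------------------------------------------------------
  districts <- NULL
  if (!is.null(lookup)) {
    assignment <- run_stage("aggregate",
                            assign_districts(
                              records[records$year == year, , drop = FALSE],
                              lookup))
    method <- config$aggregation %||% "pooled"
    districts <- run_stage("aggregate", switch(
      method,
      pooled = aggregate_pooled(records[records$year == year, , drop = FALSE],
                                assignment),
      mean = aggregate_mean(est, assignment, weights = "none"),
      `weighted-mean` = aggregate_mean(est, assignment,
                                       weights = "status_denominator"),
      stop_qof("unknown aggregation method '", method, "'",
               class = "qofprev_bad_config")))
    agg_out <- as.data.frame(districts)
    total <- attr(districts, "grand_total")
    if (!is.null(total)) agg_out <- rbind(agg_out, total)
    utils::write.csv(agg_out, file.path(outdir, "districts.csv"),
                     row.names = FALSE)
    log$stages <- c(log$stages, "aggregate")
  } else {
    qp_inform("no postcode lookup: aggregation stage skipped", quiet = quiet)
  }

  # --- agree ----------------------------------------------------------
  agreement <- NULL
  calibration <- NULL
  if (!is.null(districts) && !is.null(survey)) {
    merged <- merge(as.data.frame(districts), as.data.frame(survey),
                    by = "district_code")
    agreement <- run_stage("agree", bland_altman(
      merged$prevalence.x * 100, merged$prevalence.y * 100,
      ids = merged$district_code))
    summ <- data.frame(n_pairs = agreement$n_pairs,
                       pearson_r = agreement$pearson_r,
                       lin_ccc = agreement$lin_ccc,
                       mean_difference = agreement$mean_difference,
                       loa_lower = agreement$loa_lower,
                       loa_upper = agreement$loa_upper)
    utils::write.csv(summ, file.path(outdir, "agreement.csv"),
                     row.names = FALSE)
    utils::write.csv(agreement$table,
                     file.path(outdir, "agreement_pairs.csv"),
                     row.names = FALSE)
    log$stages <- c(log$stages, "agree")
  } else {
    qp_inform("no survey estimates: agreement stage skipped", quiet = quiet)
  }
  ok_cal <- !is.na(est$prevalence_chronic) & !is.na(est$prevalence_general)
  if (sum(ok_cal) >= 10) {
    calibration <- run_stage("agree", fit_calibration(
      est$prevalence_chronic[ok_cal] * 100,
      est$prevalence_general[ok_cal] * 100,
      threshold = config$outlier_threshold %||% 3,
      ids = est$practice_id[ok_cal]))
  }

  # --- model ----------------------------------------------------------
  model <- NULL
  if (!is.null(covars)) {
    mc <- config$model %||% list()
    base_cov <- mc$covariates %||% c("deprivation", "pct_white", "pct_over65")
    add_cov <- mc$add %||% "smoking_prev"
    model <- run_stage("model", compare_models(
      covars, base_cov, add_cov, offset = mc$offset %||% "log_exposure"))
    utils::write.csv(model$table, file.path(outdir, "model_irr.csv"),
                     row.names = FALSE)
    log$stages <- c(log$stages, "model")
  } else {
    qp_inform("no covariate table: model stage skipped", quiet = quiet)
  }

  # --- report ---------------------------------------------------------
  report <- c(
    "qofprev pipeline report",
    paste0("seed: ", seed, "; year: ", year),
    paste0("stages run: ", paste(log$stages, collapse = " -> ")),
    sprintf("practice estimates: n=%d, median prevalence %.1f%% (range %.1f-%.1f%%)",
            nrow(est), stats::median(est$prevalence_general, na.rm = TRUE) * 100,
            min(est$prevalence_general, na.rm = TRUE) * 100,
            max(est$prevalence_general, na.rm = TRUE) * 100),
    if (!is.null(districts))
      sprintf("districts: n=%d, grand-total prevalence %.1f%%",
              nrow(districts),
              attr(districts, "grand_total")$prevalence * 100),
    if (!is.null(agreement))
      sprintf("agreement vs survey: mean difference %.2f pp (LoA %.2f, %.2f), CCC %.3f",
              agreement$mean_difference, agreement$loa_lower,
              agreement$loa_upper, agreement$lin_ccc),
    if (!is.null(calibration))
      sprintf("calibration: general = %.2f + %.3f * chronic (n=%d, %d outlier(s) removed)",
              calibration$intercept, calibration$slope, calibration$n_used,
              length(calibration$removed_ids)),
    if (!is.null(model))
      sprintf("model: added-covariate LRT %.2f (p=%.3g)",
              model$lrt$statistic, model$lrt$p_value)
  )
  writeLines(report, file.path(outdir, "report.txt"))
  excl <- attr(records, "exclusions")
  log$exclusions <- if (is.null(excl)) list() else excl
  writeLines(as.character(yaml::as.yaml(
    list(seed = seed, year = year, stages = log$stages,
         n_practices = log$n_practices))),
    file.path(outdir, "run_log.yaml"))
  invisible(list(estimates = est, districts = districts,
                 agreement = agreement, calibration = calibration,
                 model = model, log = log))
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `estimate`, `aggregate`, `agree`, `model`,
#' `run`. Flags are `--key value` pairs; see the pipeline vignette. An
#' executable wrapper is installed under `inst/cli/qofprev`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
qof_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: qofprev <simulate|estimate|aggregate|agree|model|run> [--flag value ...]",
    "  simulate  --seed S --years N --outdir DIR [--practices N]",
    "  estimate  --data registry.csv --year YYYY/YYYY --out estimates.csv",
    "            [--variant status-denominator|list-based]",
    "  aggregate --data registry.csv --lookup lookup.csv --year YYYY/YYYY",
    "            --out districts.csv [--method pooled|mean|weighted-mean]",
    "  agree     --pairs pairs.csv --out summary.csv [--outlier-threshold T]",
    "  model     --data covariates.csv --covariates a,b,c --add smoking_prev",
    "            --out irr.csv [--offset log_exposure|none]",
    "  run       --config config.yaml",
    sep = "\n")
  if (length(args) == 0) {
    cat(usage, "\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  flags <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    if (startsWith(rest[i], "--")) {
      flags[[substring(rest[i], 3)]] <- rest[i + 1]
      i <- i + 2
    } else i <- i + 1
  }
  get_flag <- function(name, default = NULL) flags[[name]] %||% default

  status <- switch(
    cmd,
    simulate = {
      cfg <- cohort_config(
        n_practices = as.integer(get_flag("practices", 215)),
        seed = as.integer(get_flag("seed", 1)))
      outdir <- get_flag("outdir", ".")
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      n_years <- as.integer(get_flag("years", 1))
      if (n_years > 1) {
        my <- generate_multiyear(cfg, n_years = n_years)
        write_indicator_table(my$records, file.path(outdir, "registry.csv"))
        utils::write.csv(my$lookup, file.path(outdir, "lookup.csv"),
                         row.names = FALSE)
      } else {
        reg <- generate_registry(cfg)
        write_indicator_table(reg$records, file.path(outdir, "registry.csv"))
        utils::write.csv(reg$lookup, file.path(outdir, "lookup.csv"),
                         row.names = FALSE)
        utils::write.csv(as.data.frame(
          generate_survey_estimates(reg$truth, cfg$survey_sample_size,
                                    seed = cfg$seed)),
          file.path(outdir, "survey.csv"), row.names = FALSE)
        utils::write.csv(as.data.frame(
          generate_mortality(reg$truth, seed = cfg$seed)),
          file.path(outdir, "covariates.csv"), row.names = FALSE)
        utils::write.csv(reg$truth$practices,
                         file.path(outdir, "ground_truth.csv"),
                         row.names = FALSE)
      }
      0L
    },
    estimate = {
      records <- read_indicator_table(get_flag("data"))
      yr <- get_flag("year")
      if (!is.null(yr)) records <- records[records$year == yr, , drop = FALSE]
      est <- derive_practice_estimates(
        records, variant = get_flag("variant", "status-denominator"))
      utils::write.csv(as.data.frame(est), get_flag("out", "estimates.csv"),
                       row.names = FALSE)
      0L
    },
    aggregate = {
      records <- read_indicator_table(get_flag("data"))
      yr <- get_flag("year")
      if (!is.null(yr)) records <- records[records$year == yr, , drop = FALSE]
      lookup <- read_postcode_lookup(get_flag("lookup"))
      assignment <- assign_districts(records, lookup)
      method <- get_flag("method", "pooled")
      agg <- switch(method,
                    pooled = aggregate_pooled(records, assignment),
                    mean = aggregate_mean(derive_practice_estimates(records),
                                          assignment, weights = "none"),
                    `weighted-mean` = aggregate_mean(
                      derive_practice_estimates(records), assignment,
                      weights = "status_denominator"),
                    stop_qof("unknown method ", method,
                             class = "qofprev_bad_config"))
      out <- rbind(as.data.frame(agg), attr(agg, "grand_total"))
      utils::write.csv(out, get_flag("out", "districts.csv"),
                       row.names = FALSE)
      0L
    },
    agree = {
      pairs <- utils::read.csv(get_flag("pairs"))
      stopifnot(ncol(pairs) >= 3)
      ba <- bland_altman(pairs[[2]], pairs[[3]], ids = pairs[[1]])
      summ <- data.frame(n_pairs = ba$n_pairs, pearson_r = ba$pearson_r,
                         lin_ccc = ba$lin_ccc,
                         mean_difference = ba$mean_difference,
                         loa_lower = ba$loa_lower, loa_upper = ba$loa_upper)
      utils::write.csv(summ, get_flag("out", "agreement.csv"),
                       row.names = FALSE)
      utils::write.csv(ba$table, sub("\\.csv$", "_pairs.csv",
                                     get_flag("out", "agreement.csv")),
                       row.names = FALSE)
      0L
    },
    model = {
      covars <- read_covariate_table(get_flag("data"))
      base_cov <- strsplit(get_flag("covariates"), ",")[[1]]
      add_cov <- get_flag("add")
      offset <- get_flag("offset", "log_exposure")
      res <- if (is.null(add_cov)) {
        fit_negative_binomial(covars, base_cov, offset = offset)
      } else {
        compare_models(covars, base_cov, add_cov, offset = offset)
      }
      utils::write.csv(res$table, get_flag("out", "irr.csv"),
                       row.names = FALSE)
      0L
    },
    run = {
      run_pipeline(get_flag("config"))
      0L
    },
    {
      cat("unknown subcommand '", cmd, "'\n", usage, "\n", sep = "")
      1L
    })
  invisible(status)
}
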