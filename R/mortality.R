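# Negative binomial regression of premature CHD death counts on practice
# covariates, reported as incidence rate ratios (IRRs).
#
# NB2 parameterization: Var(Y) = mu + alpha * mu^2, log link. alpha is the
# reciprocal of MASS's theta. Maximum-likelihood dispersion by default
# (MASS::glm.nb); a fixed dispersion can be supplied, with alpha = 0
# collapsing to Poisson regression.

#' Fit a negative binomial mortality model
#'
#' @param data a `practice_covariates` data frame: `death_count`,
#'   `exposure`, and one numeric column per covariate.
#' @param covariates character vector of covariate column names.
#' @param response name of the count response (default `"death_count"`).
#' @param offset `"log_exposure"` (default) to include `log(exposure)` as
#'   an offset, or `"none"` for the covariate-only layout.
#' @param dispersion `NULL` for maximum-likelihood NB2 dispersion, `0` for
#'   Poisson, or a fixed positive alpha.
#' @return object of class `mortality_fit`: `table` (term, IRR, 2.5%/97.5%
#'   Wald bounds on the exponentiated scale, p value), `alpha`,
#'   `log_likelihood`, `n`, `offset`, `model`.
#' @export
fit_negative_binomial <- function(data, covariates,
                                  response = "death_count",
                                  offset = c("log_exposure", "none"),
                                  dispersion = NULL) {
  offset <- match.arg(offset)
  stopifnot(is.data.frame(data), length(covariates) >= 1)
  missing_cols <- setdiff(c(response, covariates), names(data))
  if (length(missing_cols)) {
    stop_qof("missing column(s): ", paste(missing_cols, collapse = ", "),
             class = "qofprev_bad_value")
  }
  sub <- data[, c(response, covariates), drop = FALSE]
  if (anyNA(sub)) {
    stop_qof("missing covariate or response values are not allowed",
             class = "qofprev_bad_value")
  }
  n <- nrow(sub)
  if (n <= length(covariates) + 2) {
    stop_qof("too few observations (", n, ") for ", length(covariates),
             " covariates", class = "qofprev_insufficient_data")
  }
  constant <- covariates[vapply(covariates,
                                function(v) stats::sd(data[[v]]) == 0,
                                logical(1))]
  if (length(constant)) {
    stop_qof("zero-variance covariate(s): ",
             paste(constant, collapse = ", "),
             class = "qofprev_collinear")
  }
  mm <- stats::model.matrix(
    stats::reformulate(covariates, intercept = TRUE), data = data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop_qof("collinear covariate(s): ", paste(aliased, collapse = ", "),
             class = "qofprev_collinear")
  }
  if (offset == "log_exposure") {
    if (!("exposure" %in% names(data)) || any(data$exposure <= 0)) {
      stop_qof("offset = 'log_exposure' needs a positive exposure column",
               class = "qofprev_bad_value")
    }
    fml <- stats::reformulate(c(covariates, "offset(log(exposure))"),
                              response = response)
  } else {
    fml <- stats::reformulate(covariates, response = response)
  }

  if (is.null(dispersion)) {
    fit <- withCallingHandlers(
      tryCatch(MASS::glm.nb(fml, data = data, maxit = 100),
               error = function(e) {
                 stop_qof("negative binomial fit failed to converge: ",
                          conditionMessage(e),
                          class = "qofprev_nonconvergence")
               }),
      warning = function(w) {
        # glm.nb warns on its theta iteration limit when alpha -> 0; the
        # coefficient estimates are still the Poisson-limit MLEs
        if (grepl("iteration limit|alternation", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (!fit$converged) {
      stop_qof("negative binomial IRLS did not converge after ",
               fit$iter, " iterations", class = "qofprev_nonconvergence")
    }
    alpha <- 1 / fit$theta
  } else {
    stopifnot(is.numeric(dispersion), length(dispersion) == 1, dispersion >= 0)
    fam <- if (dispersion == 0) stats::poisson(link = "log") else
      MASS::negative.binomial(theta = 1 / dispersion, link = "log")
    fit <- stats::glm(fml, data = data, family = fam)
    if (!fit$converged) {
      stop_qof("fixed-dispersion fit did not converge",
               class = "qofprev_nonconvergence")
    }
    alpha <- dispersion
  }

  cf <- summary(fit)$coefficients
  tab <- data.frame(
    term = rownames(cf),
    irr = exp(cf[, "Estimate"]),
    ci_lower = exp(cf[, "Estimate"] - 1.96 * cf[, "Std. Error"]),
    ci_upper = exp(cf[, "Estimate"] + 1.96 * cf[, "Std. Error"]),
    p_value = cf[, 4],
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  out <- list(table = tab, alpha = alpha,
              log_likelihood = as.numeric(stats::logLik(fit)),
              n = n, offset = offset, covariates = covariates, model = fit)
  class(out) <- "mortality_fit"
  out
}

#' @export
print.mortality_fit <- function(x, ...) {
  cat("Negative binomial mortality model (n = ", x$n,
      ", dispersion alpha = ", signif(x$alpha, 3), ")\n", sep = "")
  tab <- x$table
  tab$irr <- sprintf("%.3f", tab$irr)
  tab$ci <- sprintf("(%.3f to %.3f)", x$table$ci_lower, x$table$ci_upper)
  tab$p <- ifelse(x$table$p_value < 1e-4, "<0.0001",
                  sprintf("%.3f", x$table$p_value))
  print(tab[, c("term", "irr", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' Compare mortality models with and without an added covariate
#'
#' Fits the base covariate set and the base set plus `added_covariate` on
#' the same observations, and reports the side-by-side IRR table (the
#' with/without layout), the per-covariate IRR change, and the
#' likelihood-ratio statistic for the added term.
#'
#' @param data a `practice_covariates` data frame.
#' @param base_covariates covariate names for the base model.
#' @param added_covariate single covariate name to add (must not already be
#'   in the base set).
#' @param ... passed to [fit_negative_binomial()] (offset, dispersion...).
#' @return object of class `model_comparison`: `table` (term, irr_base,
#'   irr_with, their CIs and p values, irr_change), `lrt` (statistic, df,
#'   p_value), `fit_base`, `fit_with`.
#' @export
compare_models <- function(data, base_covariates, added_covariate, ...) {
  stopifnot(length(added_covariate) == 1)
  if (added_covariate %in% base_covariates) {
    stop_qof("covariate '", added_covariate, "' is already in the base set",
             class = "qofprev_bad_value")
  }
  fit_base <- fit_negative_binomial(data, base_covariates, ...)
  fit_with <- fit_negative_binomial(data, c(base_covariates, added_covariate),
                                    ...)
  if (fit_base$n != fit_with$n) {
    stop_qof("fits used differing observation sets",
             class = "qofprev_bad_value")
  }
  tb <- fit_base$table
  tw <- fit_with$table
  merged <- merge(tb, tw, by = "term", all = TRUE,
                  suffixes = c("_base", "_with"))
  merged$irr_change <- merged$irr_with - merged$irr_base
  ord <- match(tw$term, merged$term)
  merged <- merged[ord, ]
  rownames(merged) <- NULL
  lrt_stat <- 2 * (fit_with$log_likelihood - fit_base$log_likelihood)
  out <- list(
    table = merged,
    lrt = list(statistic = lrt_stat, df = 1,
               p_value = stats::pchisq(lrt_stat, df = 1, lower.tail = FALSE)),
    fit_base = fit_base, fit_with = fit_with
  )
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (added covariate LRT: stat = ",
      signif(x$lrt$statistic, 4), ", p = ", signif(x$lrt$p_value, 3),
      ")\n", sep = "")
  tab <- x$table
  show <- data.frame(
    term = tab$term,
    `IRR without` = sprintf("%.3f", tab$irr_base),
    `IRR with` = sprintf("%.3f", tab$irr_with),
    change = sprintf("%+.3f", tab$irr_change),
    check.names = FALSE
  )
  print(show, row.names = FALSE)
  invisible(x)
}
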