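# Agreement statistics for paired prevalence estimates: Pearson
# correlation, Lin's concordance correlation coefficient, Bland-Altman
# limits of agreement, and the chronic-to-general calibration regression
# with iterative outlier removal.
#
# Sign convention throughout: differences are first argument minus second.
# Callers pass (QOF aggregate, survey) or (chronic, general) to obtain the
# conventional signs.

#' Pearson correlation with significance test
#'
#' Thin wrapper around [stats::cor.test()] that enforces the module's
#' preconditions (length >= 3, non-constant series).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) {
    stop_qof("need at least 3 pairs", class = "qofprev_insufficient_data")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_qof("correlation undefined for a constant series",
             class = "qofprev_undefined_estimate")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Lin's concordance correlation coefficient
#'
#' CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2) with moment
#' (1/n) variance estimators, Lin's original form. Penalizes both
#' dispersion and location shifts, so |CCC| <= |Pearson r|. Degenerate
#' cases: two identical constant series have CCC 1; two unequal constant
#' series 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return scalar concordance value in \[-1, 1\].
#' @examples
#' lin_ccc(c(1, 2, 3), c(3, 4, 5)) # 0.25
#' @export
lin_ccc <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) {
    stop_qof("need at least 3 pairs", class = "qofprev_insufficient_data")
  }
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) return(1)  # identical constant series
  2 * sxy / denom
}

#' Bland-Altman agreement summary
#'
#' Differences d = x - y; mean difference, sample-sd of differences and
#' 95% limits of agreement mean(d) +/- 1.96 sd(d) (fixed multiplier, the
#' classic presentation). Pearson r and Lin's CCC of the pair are included,
#' plus the per-pair (mean, difference) table for plotting.
#'
#' @param x,y numeric vectors of equal length >= 3 (same units, e.g.
#'   percentage points).
#' @param ids optional identifiers for the pairs.
#' @return object of class `agreement_summary`: `n_pairs`, `pearson_r`,
#'   `lin_ccc`, `mean_difference`, `sd_difference`, `loa_lower`,
#'   `loa_upper`, `table` (id, mean, difference).
#' @export
bland_altman <- function(x, y, ids = NULL) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) {
    stop_qof("need at least 3 pairs", class = "qofprev_insufficient_data")
  }
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  r <- if (stats::sd(x) > 0 && stats::sd(y) > 0)
    stats::cor(x, y) else NA_real_
  out <- list(
    n_pairs = length(x),
    pearson_r = r,
    lin_ccc = lin_ccc(x, y),
    mean_difference = md,
    sd_difference = sdd,
    loa_lower = md - 1.96 * sdd,
    loa_upper = md + 1.96 * sdd,
    table = data.frame(id = ids %||% seq_along(x),
                       mean = (x + y) / 2, difference = d)
  )
  class(out) <- "agreement_summary"
  out
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat("Agreement summary (", x$n_pairs, " pairs)\n", sep = "")
  cat(sprintf("  mean difference: %.2f (95%% limits of agreement %.2f, %.2f)\n",
              x$mean_difference, x$loa_lower, x$loa_upper))
  cat(sprintf("  Pearson r: %.3f   Lin's CCC: %.3f\n",
              x$pearson_r, x$lin_ccc))
  invisible(x)
}

#' @describeIn bland_altman Bland-Altman plot: per-pair mean vs difference
#'   with the mean-difference line (solid) and 95% limits (dashed).
#' @param main,... passed to [graphics::plot()].
#' @export
plot.agreement_summary <- function(x, main = "Bland-Altman plot", ...) {
  graphics::plot(x$table$mean, x$table$difference,
                 xlab = "Mean of pair", ylab = "Difference", main = main, ...)
  graphics::abline(h = x$mean_difference, lty = 1)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), lty = 2)
  invisible(x)
}

#' Calibration regression with iterative outlier removal
#'
#' Ordinary least squares of the general-population prevalence on the
#' chronic-condition prevalence. Points with |externally studentized
#' residual| above `threshold` (default 3) are removed and the model
#' refitted, iterating until none remain. `threshold = Inf` is plain OLS.
#'
#' @param chronic,general numeric vectors of equal length >= 10.
#' @param threshold studentized-residual cutoff (default 3).
#' @param ids optional point identifiers (default indices).
#' @return object of class `calibration_fit`: `slope`, `intercept`,
#'   `n_used`, `removed_ids`, `residual_sd`, `model` (the final `lm`).
#' @export
fit_calibration <- function(chronic, general, threshold = 3, ids = NULL) {
  stopifnot(length(chronic) == length(general), threshold > 0)
  if (length(chronic) < 10) {
    stop_qof("need at least 10 pairs", class = "qofprev_insufficient_data")
  }
  if (stats::sd(chronic) == 0) {
    stop_qof("degenerate predictor: chronic series is constant",
             class = "qofprev_undefined_estimate")
  }
  ids <- ids %||% seq_along(chronic)
  keep <- rep(TRUE, length(chronic))
  # summary.lm warns on an exact fit; that case is legitimate here
  lm_sigma <- function(fit) withCallingHandlers(
    summary(fit)$sigma,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  repeat {
    df <- data.frame(chronic = chronic[keep], general = general[keep])
    fit <- stats::lm(general ~ chronic, data = df)
    if (!is.finite(threshold)) break
    # an (essentially) exact fit has no outliers; studentizing floating-
    # point noise would flag arbitrary points
    if (lm_sigma(fit) <= 1e-10 * max(1, mean(abs(df$general)))) break
    t_ext <- stats::rstudent(fit)
    out <- abs(t_ext) > threshold
    if (!any(out, na.rm = TRUE)) break
    keep[which(keep)][which(out)] <- FALSE
    if (sum(keep) < 4) {
      stop_qof("outlier removal left too few points",
               class = "qofprev_insufficient_data")
    }
  }
  res <- list(
    slope = unname(stats::coef(fit)[["chronic"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    n_used = sum(keep),
    removed_ids = ids[!keep],
    residual_sd = lm_sigma(fit),
    model = fit
  )
  class(res) <- "calibration_fit"
  res
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration fit: general = %.3f + %.3f * chronic\n",
              x$intercept, x$slope))
  cat("  n used:", x$n_used, " removed:",
      if (length(x$removed_ids)) paste(x$removed_ids, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Pairwise year-over-year concordance
#'
#' For every pair of years computes Lin's CCC and the mean difference
#' (earlier year minus later year) across the aligned practices.
#'
#' @param estimates_by_year numeric matrix, practices x years (no missing
#'   cells — apply the complete-series filter first; see
#'   [prevalence_matrix()]).
#' @return data frame: `year_a`, `year_b`, `n`, `ccc`, `mean_difference`.
#' @export
yearly_concordance <- function(estimates_by_year) {
  m <- as.matrix(estimates_by_year)
  if (ncol(m) < 2) {
    stop_qof("need at least 2 years", class = "qofprev_insufficient_data")
  }
  if (anyNA(m)) {
    stop_qof("practice sets are misaligned across years",
             class = "qofprev_misaligned")
  }
  yrs <- colnames(m) %||% as.character(seq_len(ncol(m)))
  pairs <- utils::combn(ncol(m), 2)
  out <- data.frame(
    year_a = yrs[pairs[1, ]],
    year_b = yrs[pairs[2, ]],
    n = nrow(m),
    ccc = apply(pairs, 2, function(p) lin_ccc(m[, p[1]], m[, p[2]])),
    mean_difference = apply(pairs, 2, function(p) mean(m[, p[1]] - m[, p[2]])),
    stringsAsFactors = FALSE
  )
  out
}
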