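#' @keywords internal
"_PACKAGE"

#' Render a proportion as a percentage rounded half-up
#'
#' QOF publications and the downstream prevalence tables print percentages
#' rounded half-up to one decimal place (a trailing zero may be appended in
#' print, e.g. "30.30%" for 30.3). Internal storage is always the
#' full-precision proportion; this is the presentation layer.
#'
#' @param p numeric vector of proportions in \[0, 1\] (NA allowed).
#' @param digits decimal places of the percentage (default 1).
#' @return numeric vector of percentages.
#' @examples
#' render_percent(1129 / 3721) # 30.3
#' @export
render_percent <- function(p, digits = 1) {
  stopifnot(is.numeric(p), digits >= 0)
  scale <- 10^digits
  x <- p * 100 * scale
  # round half away from zero, not banker's rounding
  sign(x) * floor(abs(x) + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# INFO-level logging, silenced by options(qofprev.quiet = TRUE) or quiet arg
qp_inform <- function(..., quiet = getOption("qofprev.quiet", FALSE)) {
  if (!isTRUE(quiet)) message("[qofprev] ", ...)
  invisible(NULL)
}

stop_qof <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "qofprev_error")))
}

check_count <- function(x, name) {
  bad <- !is.na(x) & (x < 0 | x != floor(x))
  if (any(bad)) {
    stop_qof(name, " must be a non-negative integer count (offending values: ",
             paste(utils::head(x[bad], 5), collapse = ", "), ")",
             class = "qofprev_invalid_count")
  }
  invisible(x)
}
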