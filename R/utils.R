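# Shared helpers: classed errors and display rounding.

ade_error <- function(message, class) {
  stop(structure(
    list(message = message, call = NULL),
    class = c(class, "adescale_error", "error", "condition")
  ))
}

stop_domain <- function(message) ade_error(message, "ade_domain_error")
stop_usage <- function(message) ade_error(message, "ade_usage_error")

#' Round half away from zero
#'
#' Rounding used for display throughout the package: halves move away from
#' zero (so 7.93 -> 7.9, -8.14 -> -8, 0.25 -> 0.3 at one decimal), matching
#' the convention of the published clearance tables rather than the
#' round-half-even rule of [base::round()].  All model arithmetic is done in
#' full double precision; this is a formatting concern only.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_away(7.93, 1)   # 7.9
#' round_half_away(-8.14, 0)  # -8
#' round_half_away(0.25, 1)   # 0.3 (base::round gives 0.2)
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Format a clearance or a percent error for display
#'
#' Clearances print with one decimal, percent errors as signed integers,
#' both rounded half away from zero.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @examples
#' format_clearance(7.9328)  # "7.9"
#' format_percent(-7.758)    # "-8"
#' @export
format_clearance <- function(x) {
  formatC(round_half_away(x, 1), format = "f", digits = 1)
}

#' @rdname format_clearance
#' @export
format_percent <- function(x) {
  sprintf("%d", as.integer(round_half_away(x, 0)))
}

# Maturity enumeration; preterm/term are only meaningful in the first
# 0.25 years of life.
maturity_levels <- function() c("preterm", "term", "not_applicable")

check_maturity <- function(maturity) {
  bad <- !maturity %in% maturity_levels()
  if (any(bad)) {
    stop_usage(sprintf(
      "unknown maturity value(s): %s (expected one of %s)",
      paste(unique(maturity[bad]), collapse = ", "),
      paste(maturity_levels(), collapse = ", ")
    ))
  }
  invisible(maturity)
}
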