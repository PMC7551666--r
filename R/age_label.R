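# Parsing of the age-group labels used in published pediatric PK tables:
# single ages ("2.9", "7 years"), ranges ("6-12 y", ">5-<12 year",
# "2-5.9"), open-ended forms ("<2", ">12"), months ("12.3 months",
# "11-31 months") and day-based neonatal labels ("<30 days",
# "31 days <2").

DAYS_PER_YEAR <- 365
MONTHS_PER_YEAR <- 12

#' Parse an age-group label into an age interval
#'
#' Converts a textual age label to a numeric interval `[lower_age,
#' upper_age]` in years, with a representative age at the arithmetic
#' midpoint (single ages represent themselves).  Open-ended labels use 0
#' years as the implicit lower limit (`"<2"`) and 18 years as the implicit
#' upper limit (`">12"`).  En dashes are treated as hyphens; `y`, `yr`,
#' `year(s)`, `month(s)` and `day(s)` unit suffixes are understood (months
#' divide by 12, days by 365).
#'
#' @param raw_text A single label string.
#' @return An object of class `age_label`: list with `raw_text`,
#'   `lower_age`, `upper_age`, `representative_age` (years).
#' @examples
#' parse_age_label("6-12 y")$representative_age    # 9
#' parse_age_label("12.3 months")$representative_age  # 1.025
#' @export
parse_age_label <- function(raw_text) {
  if (!is.character(raw_text) || length(raw_text) != 1 || is.na(raw_text)) {
    ade_error("'raw_text' must be a single string", "ade_parse_error")
  }
  txt <- gsub("–|—", "-", raw_text)
  txt <- tolower(trimws(gsub("\\s+", " ", txt)))

  num <- "([0-9]*\\.?[0-9]+)"
  yr <- "(?:\\s*(?:y|yr|yrs|year|years))?"

  as_label <- function(lower, upper) {
    if (lower > upper) {
      ade_error(sprintf("age label '%s' has lower age above upper age",
                        raw_text), "ade_parse_error")
    }
    structure(
      list(raw_text = raw_text, lower_age = lower, upper_age = upper,
           representative_age = (lower + upper) / 2),
      class = "age_label"
    )
  }
  g <- function(pattern) {
    m <- regmatches(txt, regexec(paste0("^", pattern, "$"), txt))[[1]]
    if (length(m)) as.numeric(m[-1]) else NULL
  }

  # "N days <M": neonatal lower limit in days, upper in years
  if (!is.null(v <- g(paste0(num, "\\s*days?\\s*<\\s*", num, yr)))) {
    return(as_label(v[1] / DAYS_PER_YEAR, v[2]))
  }
  if (!is.null(v <- g(paste0("<\\s*", num, "\\s*days?")))) {
    return(as_label(0, v[1] / DAYS_PER_YEAR))
  }
  if (!is.null(v <- g(paste0(num, "\\s*days?")))) {
    return(as_label(v[1] / DAYS_PER_YEAR, v[1] / DAYS_PER_YEAR))
  }
  if (!is.null(v <- g(paste0(">?", num, "\\s*-\\s*<?", num,
                             "\\s*(?:months?|mo)")))) {
    return(as_label(v[1] / MONTHS_PER_YEAR, v[2] / MONTHS_PER_YEAR))
  }
  if (!is.null(v <- g(paste0(num, "\\s*(?:months?|mo)")))) {
    return(as_label(v[1] / MONTHS_PER_YEAR, v[1] / MONTHS_PER_YEAR))
  }
  if (!is.null(v <- g(paste0(">?", num, "\\s*-\\s*<?", num, yr)))) {
    return(as_label(v[1], v[2]))
  }
  if (!is.null(v <- g(paste0("<\\s*", num, yr)))) {
    return(as_label(0, v[1]))
  }
  if (!is.null(v <- g(paste0(">\\s*", num, yr)))) {
    return(as_label(v[1], 18))
  }
  if (!is.null(v <- g(paste0(num, yr)))) {
    return(as_label(v[1], v[1]))
  }
  ade_error(sprintf("cannot parse age label '%s'", raw_text),
            "ade_parse_error")
}

#' @rdname parse_age_label
#' @param label An `age_label` object.
#' @export
format_age_label <- function(label) {
  stopifnot(inherits(label, "age_label"))
  label$raw_text
}

#' @export
print.age_label <- function(x, ...) {
  cat(sprintf("'%s': [%s, %s] y, representative %s y\n", x$raw_text,
              format(x$lower_age), format(x$upper_age),
              format(x$representative_age)))
  invisible(x)
}
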