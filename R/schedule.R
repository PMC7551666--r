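# Age-dependent exponent schedule: ordered age bands carrying allometric
# exponents, plus the neonatal preterm/term pair resolved by maturity.

#' Construct an exponent schedule
#'
#' An exponent schedule maps every age in (0, 18) years (together with a
#' maturity flag below the neonatal cut-off) to one allometric exponent.
#' Bands are half-open, closed on the upper end: a band with limits
#' `(lower, upper]` claims every age strictly above `lower` up to and
#' including `upper`.  Ages at or below `neonatal_upper` take
#' `preterm_exponent` or `term_exponent` according to the subject's
#' maturity.
#'
#' @param bands A `data.frame` with columns `label`, `lower_age`,
#'   `upper_age` (years) and `exponent`, ordered by age, starting at
#'   `neonatal_upper` and covering up to 18 years with no gaps or overlaps.
#' @param preterm_exponent,term_exponent Exponents applied at ages at or
#'   below `neonatal_upper` for preterm and term neonates.
#' @param neonatal_upper Upper age limit (years, inclusive) of the neonatal
#'   stratum; 0.25 years (3 months) in the canonical schedule.
#' @return An object of class `exponent_schedule`.
#' @seealso [ade_schedule()] for the canonical schedule,
#'   [exponent_for_age()] for lookup.
#' @export
exponent_schedule <- function(bands, preterm_exponent, term_exponent,
                              neonatal_upper = 0.25) {
  required <- c("label", "lower_age", "upper_age", "exponent")
  if (!is.data.frame(bands) || !all(required %in% names(bands))) {
    stop_usage(sprintf(
      "'bands' must be a data.frame with columns %s",
      paste(required, collapse = ", ")
    ))
  }
  bands <- bands[order(bands$lower_age), required, drop = FALSE]
  if (any(bands$lower_age >= bands$upper_age)) {
    stop_domain("every band must have lower_age < upper_age")
  }
  if (any(bands$exponent <= 0) || preterm_exponent <= 0 || term_exponent <= 0) {
    stop_domain("allometric exponents must be positive")
  }
  if (neonatal_upper <= 0 || neonatal_upper >= 18) {
    stop_domain("neonatal_upper must lie strictly between 0 and 18 years")
  }
  if (abs(bands$lower_age[1] - neonatal_upper) > 1e-12) {
    stop_domain("the first band must start at the neonatal upper limit")
  }
  gaps <- abs(bands$lower_age[-1] - bands$upper_age[-nrow(bands)])
  if (any(gaps > 1e-12)) {
    stop_domain("bands must be contiguous (no gaps or overlaps)")
  }
  if (bands$upper_age[nrow(bands)] < 18) {
    stop_domain("bands must cover ages up to 18 years")
  }
  structure(
    list(
      bands = bands,
      preterm_exponent = preterm_exponent,
      term_exponent = term_exponent,
      neonatal_upper = neonatal_upper
    ),
    class = "exponent_schedule"
  )
}

#' The canonical age-dependent exponent (ADE) schedule
#'
#' Exponents by age band: 1.2 for preterm and 1.1 for term neonates up to
#' 0.25 years (3 months), 1.0 above 0.25 up to 2 years, 0.9 above 2 up to
#' 5 years, and the classical 0.75 above 5 years.  Band boundaries are
#' inclusive on the upper end, so age 2.0 scales with exponent 1.0 and age
#' 5.0 with 0.9.
#'
#' @return An `exponent_schedule` object.
#' @examples
#' sched <- ade_schedule()
#' exponent_for_age(3.5, schedule = sched)            # 0.9
#' exponent_for_age(0.1, "preterm", schedule = sched) # 1.2
#' @export
ade_schedule <- function() {
  exponent_schedule(
    bands = data.frame(
      label = c("infant_toddler", "preschool", "older_child"),
      lower_age = c(0.25, 2, 5),
      upper_age = c(2, 5, 18),
      exponent = c(1.0, 0.9, 0.75)
    ),
    preterm_exponent = 1.2,
    term_exponent = 1.1,
    neonatal_upper = 0.25
  )
}

#' Look up the allometric exponent for an age
#'
#' Resolves the exponent the schedule assigns to each age.  Ages at or
#' below the neonatal limit (0.25 years in the canonical schedule) require
#' a maturity of `"preterm"` or `"term"`; above it maturity is ignored.
#'
#' @param age Age in years, strictly between 0 and 18.  Vectorised.
#' @param maturity `"preterm"`, `"term"` or `"not_applicable"`; recycled
#'   against `age`.
#' @param schedule An [exponent_schedule()]; defaults to [ade_schedule()].
#' @return Numeric vector of exponents, one per age.
#' @examples
#' exponent_for_age(c(0.1, 1, 3.5, 10), c("preterm", rep("not_applicable", 3)))
#' # 1.2 1.0 0.9 0.75
#' @export
exponent_for_age <- function(age, maturity = "not_applicable",
                             schedule = ade_schedule()) {
  stopifnot(inherits(schedule, "exponent_schedule"))
  if (!is.numeric(age) || any(!is.finite(age))) {
    stop_domain("'age' must be finite and numeric")
  }
  if (any(age <= 0 | age >= 18)) {
    stop_domain(sprintf(
      "age must lie strictly between 0 and 18 years (got %s)",
      paste(format(age[age <= 0 | age >= 18]), collapse = ", ")
    ))
  }
  maturity <- rep_len(as.character(maturity), length(age))
  check_maturity(maturity)
  neonate <- age <= schedule$neonatal_upper
  if (any(neonate & maturity == "not_applicable")) {
    ade_error(paste0(
      "maturity ('preterm' or 'term') is required for ages at or below ",
      format(schedule$neonatal_upper), " years"
    ), "ade_missing_maturity_error")
  }
  out <- numeric(length(age))
  out[neonate & maturity == "preterm"] <- schedule$preterm_exponent
  out[neonate & maturity == "term"] <- schedule$term_exponent
  if (any(!neonate)) {
    b <- schedule$bands
    # half-open (lower, upper]: the band index is the count of lower bounds
    # strictly below the age
    idx <- vapply(age[!neonate], function(a) sum(a > b$lower_age), integer(1))
    out[!neonate] <- b$exponent[idx]
  }
  out
}

# Simulation strata: the neonatal band split by maturity, then the ordinary
# bands.  Internal; used by the synthetic-cohort generator.
schedule_strata <- function(schedule) {
  b <- schedule$bands
  rbind(
    data.frame(
      label = c("preterm_neonate", "term_neonate"),
      lower_age = 0, upper_age = schedule$neonatal_upper,
      maturity = c("preterm", "term"),
      exponent = c(schedule$preterm_exponent, schedule$term_exponent)
    ),
    data.frame(
      label = b$label, lower_age = b$lower_age, upper_age = b$upper_age,
      maturity = "not_applicable", exponent = b$exponent
    )
  )
}

#' @export
print.exponent_schedule <- function(x, ...) {
  cat("Age-dependent allometric exponent schedule\n")
  cat(sprintf("  (0, %s] y  preterm %.2g / term %.2g\n",
              format(x$neonatal_upper), x$preterm_exponent, x$term_exponent))
  for (i in seq_len(nrow(x$bands))) {
    cat(sprintf("  (%s, %s] y  %.2g  (%s)\n",
                format(x$bands$lower_age[i]), format(x$bands$upper_age[i]),
                x$bands$exponent[i], x$bands$label[i]))
  }
  invisible(x)
}
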