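# Median weight-for-age reference and weight imputation.

#' Load a median weight-for-age reference table
#'
#' The packaged table holds approximate sex-averaged median body weights at
#' selected ages from birth to 18 years (70 kg at 18 years, matching the
#' adult reference weight) for the `term` stratum, plus a short `preterm`
#' stratum (about 1-2.5 kg over the first three months).  It is synthetic
#' in the sense of being a constructed stand-in for the study-specific
#' weights behind published pediatric PK analyses, which are usually not
#' reported; supply actual weights whenever they are known.  A replacement
#' table may be given as a CSV with columns `maturity`, `age_years`,
#' `median_weight_kg`.
#'
#' @param path Path to a replacement CSV; `NULL` loads the packaged table.
#' @return A `data.frame` of class `growth_reference`.
#' @export
growth_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "growth_reference.csv",
                        package = "adescale", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("maturity", "age_years", "median_weight_kg")
  if (!all(required %in% names(tab))) {
    ade_error(sprintf("growth reference must have columns %s",
                      paste(required, collapse = ", ")), "ade_schema_error")
  }
  check_maturity(tab$maturity)
  for (m in unique(tab$maturity)) {
    s <- tab[tab$maturity == m, ]
    s <- s[order(s$age_years), ]
    if (any(diff(s$age_years) <= 0)) {
      ade_error(sprintf("ages must be strictly increasing in stratum '%s'", m),
                "ade_validation_error")
    }
    if (any(s$median_weight_kg <= 0) || any(diff(s$median_weight_kg) < 0)) {
      ade_error(sprintf(
        "weights must be positive and non-decreasing in stratum '%s'", m),
        "ade_validation_error")
    }
  }
  structure(tab[order(tab$maturity, tab$age_years), ],
            class = c("growth_reference", "data.frame"))
}

#' Impute a representative body weight from age
#'
#' Piecewise-linear interpolation of the median weight-for-age table at the
#' given age.  Preterm subjects use the `preterm` stratum; everyone else
#' (term neonates and all older children) uses the `term` stratum.  Ages
#' outside the stratum's tabulated span raise an extrapolation error rather
#' than being extended silently.
#'
#' @param age Age in years.  Vectorised.
#' @param maturity `"preterm"`, `"term"` or `"not_applicable"`; recycled.
#' @param table A [growth_reference()] table.
#' @return Imputed weight(s) in kg.
#' @examples
#' impute_weight(10)  # median weight of a 10-year-old
#' @export
impute_weight <- function(age, maturity = "not_applicable",
                          table = growth_reference()) {
  stopifnot(inherits(table, "growth_reference"))
  if (!is.numeric(age) || any(!is.finite(age))) {
    stop_domain("'age' must be finite and numeric")
  }
  maturity <- rep_len(as.character(maturity), length(age))
  check_maturity(maturity)
  stratum <- ifelse(maturity == "preterm", "preterm", "term")
  out <- numeric(length(age))
  for (m in unique(stratum)) {
    s <- table[table$maturity == m, ]
    if (nrow(s) < 2) {
      ade_error(sprintf("growth reference has no usable stratum '%s'", m),
                "ade_validation_error")
    }
    sel <- stratum == m
    a <- age[sel]
    if (any(a < min(s$age_years)) || any(a > max(s$age_years))) {
      ade_error(sprintf(
        "age outside the [%s, %s] year span of growth stratum '%s'; supply a weight instead",
        format(min(s$age_years)), format(max(s$age_years)), m),
        "ade_extrapolation_error")
    }
    out[sel] <- stats::approx(s$age_years, s$median_weight_kg, xout = a,
                              method = "linear", rule = 1)$y
  }
  out
}
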