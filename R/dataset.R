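# Curated pediatric clearance dataset: 75 published observations across 29
# therapeutic proteins (13 monoclonal antibodies, 7 polyclonal
# immunoglobulin products, 9 non-antibody proteins), with readers/writers
# for user datasets in the same schema.

# Columns a dataset cannot do without; everything else gets a default.
required_obs_cols <- function() {
  c("drug_name", "drug_class", "adult_clearance", "clearance_units",
    "observed_clearance")
}

optional_obs_defaults <- function() {
  list(
    indication = NA_character_, route = "iv", series = "",
    age_label = NA_character_, representative_age = NA_real_,
    maturity = "not_applicable", weight_kg = NA_real_,
    exponent_override = NA_real_, note = "",
    reported_predicted_clearance = NA_real_,
    reported_percent_error = NA_real_
  )
}

#' Read / write clearance observation datasets
#'
#' CSV schema (one row per observation): required columns `drug_name`,
#' `drug_class` (`monoclonal`/`polyclonal`/`non_antibody`),
#' `adult_clearance`, `clearance_units`, `observed_clearance`; optional
#' columns `indication`, `route`, `series`, `age_label`,
#' `representative_age` (years), `maturity`, `weight_kg`,
#' `exponent_override`, `note`, `reported_predicted_clearance`,
#' `reported_percent_error`.  Missing optional columns are filled with
#' defaults; unknown extra columns are preserved and survive a
#' write/read round trip.  A Unicode minus in numeric columns is
#' normalised to ASCII on read.
#'
#' @param path File path.
#' @return `read_observations()` returns a `data.frame` of class
#'   `clearance_observations`; `write_observations()` returns `path`
#'   invisibly.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required_obs_cols(), names(df))
  if (length(missing)) {
    ade_error(sprintf("dataset is missing required column(s): %s",
                      paste(missing, collapse = ", ")), "ade_schema_error")
  }
  numeric_cols <- c("adult_clearance", "observed_clearance",
                    "representative_age", "weight_kg", "exponent_override",
                    "reported_predicted_clearance", "reported_percent_error")
  for (col in intersect(numeric_cols, names(df))) {
    if (is.character(df[[col]])) {
      cleaned <- gsub("−|–", "-", trimws(df[[col]]))
      cleaned[cleaned == ""] <- NA_character_
      df[[col]] <- as.numeric(cleaned)
    }
  }
  for (col in names(optional_obs_defaults())) {
    if (!col %in% names(df)) df[[col]] <- optional_obs_defaults()[[col]]
  }
  check_maturity(df$maturity)
  bad_class <- !df$drug_class %in% c("monoclonal", "polyclonal", "non_antibody")
  if (any(bad_class)) {
    ade_error(sprintf("unknown drug_class value(s): %s",
                      paste(unique(df$drug_class[bad_class]), collapse = ", ")),
              "ade_schema_error")
  }
  class(df) <- c("clearance_observations", "data.frame")
  df
}

#' @rdname read_observations
#' @param records A `clearance_observations` data.frame.
#' @export
write_observations <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load the packaged pediatric clearance dataset
#'
#' Returns the 75 curated observations (33 monoclonal, 21 polyclonal, 21
#' non-antibody) with the published predicted clearances and percent errors
#' alongside the observed values.  By default the dataset is validated
#' against the packaged manifest (29 drugs / 75 observations; 13/7/9 drugs
#' and 33/21/21 observations by class) and every row's percent error is
#' recomputed from its observed/predicted cells and checked against the
#' reported value.
#'
#' A few curation notes: the one weight-only record (tocilizumab, 20 kg,
#' age unknown) carries `weight_kg = 20` and `exponent_override = 0.75`;
#' the three canakinumab CAPS records have no usable age and carry
#' `representative_age = NA`; neonatal immunoglobulin records
#' (Sandoglobulin, Gamimune) carry a mid-neonatal representative age of
#' 0.125 years with their printed labels preserved verbatim.
#'
#' @param path Optional path to an alternative CSV in the same schema.
#' @param validate Validate against the manifest (default `TRUE`).
#' @return A `clearance_observations` data.frame.
#' @examples
#' obs <- load_observations()
#' table(obs$drug_class)
#' @export
load_observations <- function(path = NULL, validate = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "pediatric_clearance.csv",
                        package = "adescale", mustWork = TRUE)
    expected <- packaged_manifest()
  } else {
    expected <- NULL
  }
  obs <- read_observations(path)
  if (validate) validate_observations(obs, expected = expected)
  obs
}

packaged_manifest <- function() {
  path <- system.file("extdata", "pediatric_clearance_manifest.json",
                      package = "adescale", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Validate a clearance observation dataset
#'
#' Checks positivity of clearances, legal class/maturity codes, and that
#' the percent error recomputed from the observed and predicted clearance
#' cells agrees with the reported percent error column to within
#' `tolerance` percentage points (default 5, absorbing the rounding of
#' published table cells).  Optionally compares the resulting manifest
#' (total observations, observations and distinct drugs per class) against
#' expected counts.
#'
#' @param records A `clearance_observations` data.frame.
#' @param expected Optional manifest list with elements `total_records`,
#'   `observations` and `drugs` (named per-class counts).
#' @param tolerance Allowed gap (percentage points) between recomputed and
#'   reported percent error.
#' @return The manifest, an object of class `fixture_manifest`, invisibly
#'   on validation failure an error of class `ade_validation_error` names
#'   the offending row.
#' @export
validate_observations <- function(records, expected = NULL, tolerance = 5) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    ade_error("the observation list is empty", "ade_validation_error")
  }
  row_id <- function(i) sprintf("%s [%s]", records$drug_name[i],
                                records$age_label[i])
  for (col in c("observed_clearance", "adult_clearance")) {
    bad <- which(!is.finite(records[[col]]) | records[[col]] <= 0)
    if (length(bad)) {
      ade_error(sprintf("%s must be positive: row %s", col, row_id(bad[1])),
                "ade_validation_error")
    }
  }
  bad <- which(!is.na(records$reported_predicted_clearance) &
                 records$reported_predicted_clearance <= 0)
  if (length(bad)) {
    ade_error(sprintf("reported_predicted_clearance must be positive: row %s",
                      row_id(bad[1])), "ade_validation_error")
  }
  has_pe <- !is.na(records$reported_predicted_clearance) &
    !is.na(records$reported_percent_error)
  if (any(has_pe)) {
    recomputed <- percent_error(
      records$reported_predicted_clearance[has_pe],
      records$observed_clearance[has_pe]
    )
    gap <- abs(recomputed - records$reported_percent_error[has_pe])
    if (any(gap > tolerance)) {
      i <- which(has_pe)[which.max(gap)]
      ade_error(sprintf(
        "recomputed percent error differs from the reported value by %.1f points (> %g): row %s",
        max(gap), tolerance, row_id(i)), "ade_validation_error")
    }
  }
  manifest <- structure(
    list(
      total_records = nrow(records),
      observations = as.list(table(records$drug_class)),
      drugs = lapply(split(records$drug_name, records$drug_class),
                     function(x) length(unique(x)))
    ),
    class = "fixture_manifest"
  )
  if (!is.null(expected)) {
    same <- function(a, b) {
      all(vapply(names(b), function(k) {
        !is.null(a[[k]]) && as.integer(a[[k]]) == as.integer(b[[k]])
      }, logical(1)))
    }
    ok <- manifest$total_records == expected$total_records &&
      same(manifest$observations, expected$observations) &&
      same(manifest$drugs, expected$drugs)
    if (!ok) {
      ade_error("dataset counts do not match the expected manifest",
                "ade_validation_error")
    }
  }
  invisible(manifest)
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat(sprintf("Clearance dataset: %d observations\n", x$total_records))
  for (cl in names(x$observations)) {
    cat(sprintf("  %-13s %2d observations, %2d drugs\n", cl,
                as.integer(x$observations[[cl]]), as.integer(x$drugs[[cl]])))
  }
  invisible(x)
}
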