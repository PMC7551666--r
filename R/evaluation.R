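# Prediction-accuracy evaluation: signed percent error, absolute-error
# binning at the 30%/50% acceptability thresholds, and per-class summary
# tables.

#' Signed percent prediction error
#'
#' `(predicted - observed) * 100 / observed`, at full precision.  Use
#' [format_percent()] for integer display.
#'
#' @param predicted,observed Numeric vectors (recycled); `observed` must be
#'   strictly positive.
#' @return Signed percent errors.
#' @examples
#' percent_error(7.9, 8.6)  # -8.139...
#' @export
percent_error <- function(predicted, observed) {
  if (!is.numeric(predicted) || !is.numeric(observed)) {
    stop_domain("'predicted' and 'observed' must be numeric")
  }
  if (any(!is.na(observed) & observed <= 0)) {
    stop_domain("'observed' must be strictly positive")
  }
  (predicted - observed) * 100 / observed
}

#' Bin percent errors at the 30% / 50% acceptability thresholds
#'
#' Counts observations by absolute percent error: within 30% (inclusive),
#' within 50% (inclusive), and over 50% (strict).  Inclusive upper bounds
#' make the bins a partition: an error of exactly -50% counts as
#' acceptable.  Binning is symmetric in sign.
#'
#' @param errors Numeric vector of signed percent errors (no `NA`).
#' @param thresholds Two ascending thresholds; the canonical 30/50.
#' @param rounded Bin on integer-rounded errors (half away from zero)
#'   instead of full-precision ones.  Default `FALSE`.
#' @return An object of class `error_bins`: list with `n_observations`,
#'   `n_within_30`, `n_within_50`, `n_over_50`, `min_abs_error`,
#'   `max_abs_error`, `thresholds`.
#' @examples
#' bin_errors(c(-10, 31, -50, 60))
#' @export
bin_errors <- function(errors, thresholds = c(30, 50), rounded = FALSE) {
  if (length(errors) == 0) {
    ade_error("cannot bin an empty error vector", "ade_empty_input_error")
  }
  if (any(!is.finite(errors))) {
    stop_domain("all percent errors must be finite")
  }
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  e <- abs(if (rounded) round_half_away(errors) else errors)
  structure(
    list(
      n_observations = length(e),
      n_within_30 = sum(e <= thresholds[1]),
      n_within_50 = sum(e <= thresholds[2]),
      n_over_50 = sum(e > thresholds[2]),
      min_abs_error = min(e),
      max_abs_error = max(e),
      thresholds = thresholds
    ),
    class = "error_bins"
  )
}

#' @export
print.error_bins <- function(x, ...) {
  cat(sprintf(
    "n = %d: <=%g%% PE %d (%s%%), <=%g%% PE %d (%s%%), >%g%% PE %d (%s%%)\n",
    x$n_observations,
    x$thresholds[1], x$n_within_30, format_percent(100 * x$n_within_30 / x$n_observations),
    x$thresholds[2], x$n_within_50, format_percent(100 * x$n_within_50 / x$n_observations),
    x$thresholds[2], x$n_over_50, format_percent(100 * x$n_over_50 / x$n_observations)
  ))
  cat(sprintf("absolute error range: %s%% to %s%%\n",
              format(round_half_away(x$min_abs_error, 1)),
              format(round_half_away(x$max_abs_error, 1))))
  invisible(x)
}

#' Regenerate model predictions for an observation dataset
#'
#' Adds model-based predicted clearances to a dataset: the exponent comes
#' from `exponent_override` when present, otherwise from the schedule at
#' the row's `representative_age` (with its maturity); the weight comes
#' from `weight_kg` when present, otherwise is imputed from the growth
#' reference.  Rows with neither a weight nor a usable age get `NA` with a
#' warning.
#'
#' @param records A `clearance_observations` data.frame.
#' @param schedule An [exponent_schedule()].
#' @param growth A [growth_reference()].
#' @return `records` with added columns `model_exponent`,
#'   `model_weight_kg`, `model_weight_source`, `model_predicted_clearance`.
#' @export
predict_observations <- function(records, schedule = ade_schedule(),
                                 growth = growth_reference()) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  exponent <- rep(NA_real_, n)
  weight <- rep(NA_real_, n)
  source <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    age <- records$representative_age[i]
    mat <- records$maturity[i]
    if (!is.na(records$exponent_override[i])) {
      exponent[i] <- records$exponent_override[i]
    } else if (!is.na(age)) {
      exponent[i] <- exponent_for_age(age, mat, schedule)
    }
    if (!is.na(records$weight_kg[i])) {
      weight[i] <- records$weight_kg[i]
      source[i] <- "supplied"
    } else if (!is.na(age)) {
      weight[i] <- impute_weight(age, mat, growth)
      source[i] <- "imputed"
    }
  }
  usable <- !is.na(exponent) & !is.na(weight)
  if (any(!usable)) {
    warning(sprintf(
      "%d row(s) have neither a weight nor a usable age; predictions set to NA",
      sum(!usable)), call. = FALSE)
  }
  pred <- rep(NA_real_, n)
  pred[usable] <- scale_clearance(
    records$adult_clearance[usable], weight[usable], exponent[usable]
  )
  records$model_exponent <- exponent
  records$model_weight_kg <- weight
  records$model_weight_source <- source
  records$model_predicted_clearance <- pred
  records
}

#' Per-class and overall prediction-accuracy summary
#'
#' Computes signed percent errors for every observation and bins them at
#' the 30%/50% thresholds, per drug class and overall.  With
#' `basis = "reported"` the error is recomputed from the dataset's
#' observed and reported-predicted clearance cells; with `basis = "model"`
#' predictions are regenerated from the exponent schedule and growth
#' reference via [predict_observations()] (rows without a usable age or
#' weight are dropped with a message).
#'
#' @param records A `clearance_observations` data.frame.
#' @param basis `"reported"` or `"model"`.
#' @param schedule,growth Used for `basis = "model"`.
#' @param rounded Bin on integer-rounded percent errors (default `FALSE`,
#'   i.e. full precision).
#' @return A `data.frame` of class `evaluation_summary`, one row per drug
#'   class plus `"overall"`, with bin counts and the absolute-error range.
#' @examples
#' summarize_errors(load_observations())
#' @export
summarize_errors <- function(records, basis = c("reported", "model"),
                             schedule = ade_schedule(),
                             growth = growth_reference(), rounded = FALSE) {
  basis <- match.arg(basis)
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (basis == "reported") {
    predicted <- records$reported_predicted_clearance
    if (all(is.na(predicted))) {
      stop_usage("no reported predicted clearances; use basis = \"model\"")
    }
  } else {
    predicted <- predict_observations(records, schedule, growth)$
      model_predicted_clearance
  }
  keep <- !is.na(predicted)
  if (any(!keep)) {
    message(sprintf("dropping %d observation(s) without a prediction",
                    sum(!keep)))
  }
  records <- records[keep, , drop = FALSE]
  pe <- percent_error(predicted[keep], records$observed_clearance)
  groups <- c(intersect(c("monoclonal", "polyclonal", "non_antibody"),
                        unique(records$drug_class)), "overall")
  rows <- lapply(groups, function(g) {
    sel <- if (g == "overall") rep(TRUE, nrow(records))
           else records$drug_class == g
    b <- bin_errors(pe[sel], rounded = rounded)
    data.frame(
      group = g, n_observations = b$n_observations,
      n_within_30 = b$n_within_30, n_within_50 = b$n_within_50,
      n_over_50 = b$n_over_50, min_abs_error = b$min_abs_error,
      max_abs_error = b$max_abs_error
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "basis") <- basis
  class(out) <- c("evaluation_summary", "data.frame")
  out
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("Prediction-accuracy summary (basis: %s)\n",
              attr(x, "basis") %||% "unknown"))
  pct <- function(k, n) sprintf("%d (%s%%)", k, format_percent(100 * k / n))
  hdr <- sprintf("  %-13s %5s %12s %12s %12s %16s", "group", "n",
                 "<=30% PE", "<=50% PE", ">50% PE", "|PE| range")
  cat(hdr, "\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-13s %5d %12s %12s %12s %7s-%s%%\n",
                x$group[i], x$n_observations[i],
                pct(x$n_within_30[i], x$n_observations[i]),
                pct(x$n_within_50[i], x$n_observations[i]),
                pct(x$n_over_50[i], x$n_observations[i]),
                format(round_half_away(x$min_abs_error[i], 1)),
                format(round_half_away(x$max_abs_error[i], 1))))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
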