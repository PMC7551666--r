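# Allometric core: weight-based power-law scaling of clearance from a 70 kg
# adult reference, dose projection from a target exposure, and the
# fixed-exponent comparator.

#' Describe a drug's adult clearance reference
#'
#' Bundles the adult (reference) clearance of a therapeutic protein with its
#' units, class and the standard adult body weight.  Units are carried
#' through predictions verbatim and never converted: the scaling factor
#' `(W/70)^b` is dimensionless, so predictions inherit whatever units the
#' adult clearance was reported in (mL/h, mL/day, L/h, mL/min, ...).
#'
#' @param drug_name Drug name.
#' @param adult_clearance Mean adult clearance, positive.
#' @param clearance_units Units string, echoed verbatim on every prediction.
#' @param drug_class One of `"monoclonal"`, `"polyclonal"`, `"non_antibody"`.
#' @param route Route of administration (free text, default `"iv"`).
#' @param indication Indication (free text, optional).
#' @param reference_weight Standard adult weight in kg, default 70.
#' @return An object of class `adult_reference`.
#' @examples
#' adult_reference("tocilizumab", 20.3, "mL/h")
#' @export
adult_reference <- function(drug_name, adult_clearance, clearance_units,
                            drug_class = c("monoclonal", "polyclonal",
                                           "non_antibody"),
                            route = "iv", indication = NA_character_,
                            reference_weight = 70) {
  drug_class <- match.arg(drug_class)
  if (!is.numeric(adult_clearance) || length(adult_clearance) != 1 ||
      !is.finite(adult_clearance) || adult_clearance <= 0) {
    stop_domain("'adult_clearance' must be a single positive number")
  }
  if (!is.numeric(reference_weight) || reference_weight <= 0) {
    stop_domain("'reference_weight' must be positive")
  }
  structure(
    list(
      drug_name = as.character(drug_name),
      drug_class = drug_class,
      adult_clearance = adult_clearance,
      clearance_units = as.character(clearance_units),
      route = as.character(route),
      indication = as.character(indication),
      reference_weight = reference_weight
    ),
    class = "adult_reference"
  )
}

#' @export
print.adult_reference <- function(x, ...) {
  cat(sprintf("%s (%s): adult CL %s %s, route %s, reference weight %g kg\n",
              x$drug_name, x$drug_class, format(x$adult_clearance),
              x$clearance_units, x$route, x$reference_weight))
  invisible(x)
}

#' Allometric clearance scaling (vectorised core)
#'
#' The power law `CL_child = CL_adult * (W / W_ref)^b`.  All higher-level
#' prediction functions reduce to this line.
#'
#' @param adult_clearance Adult clearance (any units).
#' @param weight Body weight in kg, positive.
#' @param exponent Allometric exponent `b`, positive.
#' @param reference_weight Adult reference weight in kg, default 70.
#' @return Scaled clearance in the units of `adult_clearance`.
#' @examples
#' scale_clearance(20.3, 20, 0.75)  # 7.9328...
#' @export
scale_clearance <- function(adult_clearance, weight, exponent,
                            reference_weight = 70) {
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop_domain("'weight' must be positive")
  }
  if (any(!is.finite(exponent)) || any(exponent <= 0)) {
    stop_domain("'exponent' must be positive")
  }
  if (any(adult_clearance <= 0)) {
    stop_domain("'adult_clearance' must be positive")
  }
  adult_clearance * (weight / reference_weight)^exponent
}

#' Predict a child's clearance from an adult reference
#'
#' Applies `CL = adult CL * (W/70)^b` at full precision.  Use
#' [format_clearance()] for one-decimal display.
#'
#' @param reference An [adult_reference()], or a single positive number
#'   taken as an adult clearance with empty units.
#' @param weight Child body weight in kg.
#' @param exponent Allometric exponent (see [exponent_for_age()]).
#' @param weight_source `"supplied"` or `"imputed"`; bookkeeping for
#'   reports.
#' @param age,maturity Optional subject descriptors carried on the result.
#' @return An object of class `clearance_prediction` with fields
#'   `drug_name`, `age`, `maturity`, `weight_used`, `weight_source`,
#'   `exponent_used`, `predicted_clearance`, `clearance_units`.
#' @examples
#' ref <- adult_reference("tocilizumab", 20.3, "mL/h")
#' p <- predict_clearance(ref, weight = 20, exponent = 0.75)
#' format_clearance(p$predicted_clearance)  # "7.9"
#' @export
predict_clearance <- function(reference, weight, exponent,
                              weight_source = c("supplied", "imputed"),
                              age = NA_real_, maturity = "not_applicable") {
  weight_source <- match.arg(weight_source)
  if (is.numeric(reference) && length(reference) == 1) {
    reference <- adult_reference("unspecified", reference, "")
  }
  stopifnot(inherits(reference, "adult_reference"))
  if (!is.numeric(weight) || length(weight) != 1 || !is.finite(weight) ||
      weight <= 0) {
    stop_domain("'weight' must be a single positive number (kg)")
  }
  if (!is.numeric(exponent) || length(exponent) != 1 || exponent <= 0) {
    stop_domain("'exponent' must be a single positive number")
  }
  cl <- scale_clearance(reference$adult_clearance, weight, exponent,
                        reference$reference_weight)
  structure(
    list(
      drug_name = reference$drug_name,
      age = age,
      maturity = maturity,
      weight_used = weight,
      weight_source = weight_source,
      exponent_used = exponent,
      predicted_clearance = cl,
      clearance_units = reference$clearance_units,
      reference_weight = reference$reference_weight
    ),
    class = "clearance_prediction"
  )
}

#' @export
print.clearance_prediction <- function(x, ...) {
  cat(sprintf("Predicted clearance for %s\n", x$drug_name))
  if (!is.na(x$age)) cat(sprintf("  age:      %s y (%s)\n", format(x$age), x$maturity))
  cat(sprintf("  weight:   %s kg (%s)\n", format(x$weight_used), x$weight_source))
  cat(sprintf("  exponent: %s\n", format(x$exponent_used)))
  cat(sprintf("  CL:       %s %s\n", format_clearance(x$predicted_clearance),
              x$clearance_units))
  invisible(x)
}

#' One-call pediatric clearance prediction
#'
#' Front end combining exponent lookup and weight imputation: supply an age
#' (plus maturity for neonates) and/or a weight.  A missing weight is
#' imputed from the median weight-for-age reference; a missing age means no
#' exponent can be looked up, in which case the classical 0.75 is used (the
#' convention applied to the one weight-only record in the packaged
#' dataset) unless `exponent` is given explicitly.
#'
#' @param reference An [adult_reference()].
#' @param age Age in years (optional if `weight` is given).
#' @param maturity `"preterm"`, `"term"` or `"not_applicable"`; required
#'   below 0.25 years.
#' @param weight Body weight in kg (optional if `age` is given).
#' @param exponent Optional explicit exponent overriding the schedule.
#' @param schedule An [exponent_schedule()].
#' @param growth A [growth_reference()] table for weight imputation.
#' @return A `clearance_prediction`.
#' @examples
#' ref <- adult_reference("example mAb", 55, "mL/h")
#' predict_pediatric_clearance(ref, age = 10)
#' @export
predict_pediatric_clearance <- function(reference, age = NULL,
                                        maturity = "not_applicable",
                                        weight = NULL, exponent = NULL,
                                        schedule = ade_schedule(),
                                        growth = growth_reference()) {
  if (is.null(age) && is.null(weight)) {
    stop_usage("supply at least one of 'age' or 'weight'")
  }
  if (is.null(exponent)) {
    if (!is.null(age)) {
      exponent <- exponent_for_age(age, maturity, schedule)
    } else {
      exponent <- 0.75
    }
  }
  if (is.null(weight)) {
    weight <- impute_weight(age, maturity, growth)
    source <- "imputed"
  } else {
    source <- "supplied"
  }
  predict_clearance(reference, weight, exponent, weight_source = source,
                    age = if (is.null(age)) NA_real_ else age,
                    maturity = maturity)
}

#' Project a dose from predicted clearance and a target exposure
#'
#' `Dose = CL x AUC` (from `CL = Dose/AUC`).  Units are the caller's
#' responsibility: with clearance in mL/h and a target AUC in mg.h/mL the
#' projected dose is in mg.  Units are echoed, never checked.
#'
#' @param prediction A `clearance_prediction`, or a single positive
#'   clearance value.
#' @param target_auc Target area under the concentration-time curve,
#'   positive.
#' @return An object of class `dose_projection` with `projected_dose`,
#'   `target_auc` and the clearance used.
#' @examples
#' project_dose(7.9, target_auc = 10)  # dose 79
#' @export
project_dose <- function(prediction, target_auc) {
  if (!is.numeric(target_auc) || length(target_auc) != 1 ||
      !is.finite(target_auc) || target_auc <= 0) {
    stop_domain("'target_auc' must be a single positive number")
  }
  if (is.numeric(prediction) && length(prediction) == 1) {
    if (!is.finite(prediction) || prediction <= 0) {
      stop_domain("clearance must be positive")
    }
    cl <- prediction
    units <- ""
    prediction <- NULL
  } else {
    stopifnot(inherits(prediction, "clearance_prediction"))
    cl <- prediction$predicted_clearance
    units <- prediction$clearance_units
  }
  structure(
    list(
      target_auc = target_auc,
      projected_dose = cl * target_auc,
      clearance = cl,
      clearance_units = units,
      prediction = prediction
    ),
    class = "dose_projection"
  )
}

#' @export
print.dose_projection <- function(x, ...) {
  cat(sprintf("Projected dose: %s  (CL %s %s x target AUC %s)\n",
              format(x$projected_dose), format(x$clearance),
              x$clearance_units, format(x$target_auc)))
  invisible(x)
}

#' Over-prediction factor of a fixed exponent relative to the ADE exponent
#'
#' For a child of weight `W`, the ratio of the clearance predicted with a
#' fixed exponent (classically 0.75) to the clearance predicted with the
#' age-appropriate exponent is `(W/70)^(fixed - ade)`.  For any weight
#' below the adult reference this ratio exceeds 1 whenever the ADE exponent
#' exceeds the fixed one, quantifying how strongly the fixed 0.75 model
#' over-predicts clearance in neonates, infants and toddlers.
#'
#' @param weight Body weight in kg, positive.  Vectorised.
#' @param ade_exponent Age-appropriate exponent.
#' @param fixed_exponent Fixed comparator exponent, default 0.75.
#' @param reference_weight Adult reference weight, default 70 kg.
#' @return Dimensionless ratio (fixed-model prediction / ADE prediction).
#' @examples
#' fixed_exponent_ratio(3.5, ade_exponent = 1.2)  # ~3.85 for a neonate
#' @export
fixed_exponent_ratio <- function(weight, ade_exponent, fixed_exponent = 0.75,
                                 reference_weight = 70) {
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop_domain("'weight' must be positive")
  }
  (weight / reference_weight)^(fixed_exponent - ade_exponent)
}
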