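# adescale

Pediatric clearance prediction for therapeutic proteins — monoclonal
antibodies, polyclonal immunoglobulin products and non-antibody proteins —
by weight-based allometric scaling with **age-dependent exponents** (the
ADE model), for pharmacometricians selecting first-in-pediatric doses.

Clearance drives exposure (`CL = Dose/AUC`), so a child's clearance
predicted from adult data is enough to project a starting dose for a
pediatric trial.  The model scales the mean adult clearance by body
weight,

```
CL_child = CL_adult × (W_child / 70 kg)^b
```

with an exponent that varies by age band instead of the classical fixed
0.75:

| age band                     | b    |
|------------------------------|------|
| preterm neonate (≤ 0.25 y)   | 1.2  |
| term neonate (≤ 0.25 y)      | 1.1  |
| > 0.25 – 2 y                 | 1.0  |
| > 2 – 5 y                    | 0.9  |
| > 5 y                        | 0.75 |

A fixed 0.75 over-predicts clearance in the youngest children by the
factor `(W/70)^(0.75 − b)` — almost four-fold for a 3.5 kg preterm
neonate.

The package also ships:

* a curated dataset of 75 published pediatric clearance observations for
  29 therapeutic proteins, with the published predictions and percent
  errors (`load_observations()`);
* the percent-prediction-error statistic
  `(predicted − observed) × 100 / observed` with accuracy binning at the
  30%/50% thresholds (`percent_error()`, `bin_errors()`,
  `summarize_errors()`);
* a median weight-for-age reference for imputing weights from age-group
  labels (`growth_reference()`, `impute_weight()`, `parse_age_label()`);
* a synthetic-cohort simulator and log-log exponent-recovery experiments
  (`simulate_cohort()`, `fit_allometric_exponent()`,
  `recovery_experiment()`);
* a command-line wrapper at `inst/scripts/ade.R`
  (`predict | reproduce | evaluate | simulate | recover`).

## Worked example

The one published record with an explicit weight — tocilizumab, 20 kg,
age unknown, adult CL 20.3 mL/h, exponent 0.75:

```r
library(adescale)
ref  <- adult_reference("tocilizumab", 20.3, "mL/h")
pred <- predict_clearance(ref, weight = 20, exponent = exponent_for_age(10))
pred
#> Predicted clearance for tocilizumab
#>   weight:   20 kg (supplied)
#>   exponent: 0.75
#>   CL:       7.9 mL/h
percent_error(pred$predicted_clearance, 8.6)   # observed 8.6 mL/h
#> [1] -7.757934                                # prints as -8%
project_dose(pred, target_auc = 10)
#> Projected dose: 79.33138  (CL 7.933138 mL/h x target AUC 10)
```

20.3 × (20/70)^0.75 = 7.93 mL/h: the model under-predicts the observed
8.6 mL/h by 8%, well inside the 30% acceptability threshold.  With a
target AUC the predicted clearance converts directly into a projected
dose (units are the caller's responsibility).

Evaluating the full packaged dataset against the published predictions:

```r
summarize_errors(load_observations(), basis = "reported")
#> Prediction-accuracy summary (basis: reported)
#>   group             n     <=30% PE     <=50% PE      >50% PE       |PE| range
#>   monoclonal       33     28 (85%)     32 (97%)       1 (3%)       0-57.9%
#>   polyclonal       21     18 (86%)    21 (100%)       0 (0%)       0-50%
#>   non_antibody     21     12 (57%)     19 (90%)      2 (10%)       1-77.5%
#>   overall          75     58 (77%)     72 (96%)       3 (4%)       0-77.5%
```

96% of observations fall within the 50% error threshold and only 3 of 75
exceed it — the published ≤50% counts exactly.  The ≤30% counts here are
recomputed from the rounded printed clearance cells and come out slightly
below the published ones (58 vs 60 overall): boundary rows whose
full-precision error sat just under 30% recompute to just over it.
`reproduce_reference_analysis()` prints the row-level discrepancy report
alongside this summary.  Note the published dataset's errors are signed;
binning is on absolute values.

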