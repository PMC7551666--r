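test_that("percent error is signed and full precision", {
  expect_equal(percent_error(7.9, 8.6), -8.139535, tolerance = 1e-6)
  expect_equal(format_percent(percent_error(7.9, 8.6)), "-8")
  expect_equal(percent_error(5, 5), 0)
  expect_equal(percent_error(8, 19), -57.894737, tolerance = 1e-6)
  expect_equal(percent_error(c(12, 6), c(10, 12)), c(20, -50))
  expect_error(percent_error(5, 0), class = "ade_domain_error")
  expect_error(percent_error(5, -2), class = "ade_domain_error")
})

test_that("binning is inclusive at the thresholds and partitions the data", {
  b <- bin_errors(-50)
  expect_equal(b$n_within_50, 1)
  expect_equal(b$n_over_50, 0)
  b <- bin_errors(c(-10, 60))
  expect_equal(b$n_within_50, 1)
  expect_equal(b$n_over_50, 1)
  b <- bin_errors(c(30, -30, 30.0001, 50, -50.0001))
  expect_equal(b$n_within_30, 2)
  expect_equal(b$n_within_50, 4)
  expect_equal(b$n_over_50, 1)
  expect_error(bin_errors(numeric(0)), class = "ade_empty_input_error")
  expect_error(bin_errors(c(1, NA)), class = "ade_domain_error")
})

test_that("bin counts agree with a brute-force recount on random vectors", {
  recount <- function(e) {
    # independent oracle: explicit element-by-element tally
    within30 <- 0; within50 <- 0; over50 <- 0
    for (x in e) {
      if (abs(x) <= 30) within30 <- within30 + 1
      if (abs(x) <= 50) within50 <- within50 + 1 else over50 <- over50 + 1
    }
    c(within30, within50, over50)
  }
  set.seed(4711)
  for (i in 1:25) {
    e <- round(stats::rnorm(sample(1:60, 1), 0, 40), sample(0:2, 1))
    b <- bin_errors(e)
    expect_equal(c(b$n_within_30, b$n_within_50, b$n_over_50), recount(e))
    expect_equal(b$n_within_50 + b$n_over_50, b$n_observations)
    expect_lte(b$n_within_30, b$n_within_50)
  }
})

test_that("rounded-basis binning moves only boundary errors", {
  e <- c(50.4, 50.6, 30.3, -29.6)
  full <- bin_errors(e)
  rounded <- bin_errors(e, rounded = TRUE)
  expect_equal(full$n_over_50, 2)
  expect_equal(rounded$n_over_50, 1)   # 50.4 rounds to 50
  expect_equal(full$n_within_30, 1)
  expect_equal(rounded$n_within_30, 2) # 30.3 rounds in to the 30 boundary
})

test_that("the reported-basis summary reproduces the published accuracy table", {
  s <- summarize_errors(load_observations(), basis = "reported")
  get <- function(g, col) s[s$group == g, col]
  expect_equal(get("overall", "n_observations"), 75)
  expect_equal(get("overall", "n_within_50"), 72)
  expect_equal(get("overall", "n_over_50"), 3)
  expect_equal(get("monoclonal", "n_within_50"), 32)
  expect_equal(get("monoclonal", "n_over_50"), 1)
  expect_equal(get("polyclonal", "n_within_50"), 21)
  expect_equal(get("polyclonal", "n_over_50"), 0)
  expect_equal(get("non_antibody", "n_within_50"), 19)
  expect_equal(get("non_antibody", "n_over_50"), 2)
  # partition and nesting hold on every row
  expect_equal(s$n_within_50 + s$n_over_50, s$n_observations)
  expect_true(all(s$n_within_30 <= s$n_within_50))
})

test_that("a single zero-error record lands in the innermost bin", {
  one <- data.frame(
    drug_name = "x", drug_class = "monoclonal", adult_clearance = 10,
    clearance_units = "mL/h", observed_clearance = 5,
    reported_predicted_clearance = 5, reported_percent_error = 0
  )
  class(one) <- c("clearance_observations", "data.frame")
  one <- read_observations(write_observations(one, tempfile(fileext = ".csv")))
  s <- summarize_errors(one, basis = "reported")
  expect_equal(s[s$group == "overall", "n_within_30"], 1)
  expect_equal(s[s$group == "overall", "n_over_50"], 0)
})

test_that("model-basis evaluation regenerates predictions and drops unusable rows", {
  obs <- load_observations()
  suppressWarnings(pred <- predict_observations(obs))
  # the weight-only record uses its supplied weight and override exponent
  toci <- pred[pred$drug_name == "Tocilizumab", ]
  expect_equal(toci$model_weight_source, "supplied")
  expect_equal(toci$model_exponent, 0.75)
  expect_equal(round_half_away(toci$model_predicted_clearance, 1), 7.9)
  # exactly the three age-unknown CAPS rows are unusable
  expect_equal(sum(is.na(pred$model_predicted_clearance)), 3)
  suppressWarnings(
    expect_message(s <- summarize_errors(obs, basis = "model"),
                   "dropping 3")
  )
  expect_equal(s[s$group == "overall", "n_observations"], 72)
})
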