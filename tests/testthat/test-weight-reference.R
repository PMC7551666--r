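growth <- growth_reference()

test_that("interpolation is exact at every tabulated knot", {
  for (m in c("term", "preterm")) {
    s <- growth[growth$maturity == m, ]
    expect_equal(impute_weight(s$age_years[-1], m, growth),
                 s$median_weight_kg[-1])
  }
})

test_that("interpolation is linear and monotone between knots", {
  s <- growth[growth$maturity == "term", ]
  mid_age <- (s$age_years[5] + s$age_years[6]) / 2
  expect_equal(impute_weight(mid_age, table = growth),
               (s$median_weight_kg[5] + s$median_weight_kg[6]) / 2)
  ages <- seq(0.01, 18, length.out = 500)
  w <- impute_weight(ages, table = growth)
  expect_true(all(diff(w) >= 0))
  expect_true(all(w > 0))
})

test_that("ages outside the tabulated span are never extrapolated", {
  expect_error(impute_weight(19), class = "ade_extrapolation_error")
  expect_error(impute_weight(0.5, "preterm"),
               class = "ade_extrapolation_error")
})

test_that("a malformed growth table is rejected on load", {
  bad <- data.frame(maturity = "term", age_years = c(1, 1, 2),
                    median_weight_kg = c(9, 10, 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, path, row.names = FALSE)
  expect_error(growth_reference(path), class = "ade_validation_error")
  dec <- data.frame(maturity = "term", age_years = c(1, 2, 3),
                    median_weight_kg = c(10, 9, 12))
  write.csv(dec, path, row.names = FALSE)
  expect_error(growth_reference(path), class = "ade_validation_error")
})

test_that("age labels parse to midpoint representative ages", {
  one <- parse_age_label("2.9")
  expect_equal(one$lower_age, 2.9)
  expect_equal(one$upper_age, 2.9)
  expect_equal(one$representative_age, 2.9)
  expect_equal(parse_age_label("6-12 y")$representative_age, 9)
  expect_equal(parse_age_label("12.3 months")$representative_age, 1.025)
  expect_equal(parse_age_label("<2")$representative_age, 1)
  expect_equal(parse_age_label(">12")$upper_age, 18)
  expect_equal(parse_age_label(">5-<12 year")$representative_age, 8.5)
  expect_equal(parse_age_label("11-31 months")$representative_age, 21 / 12)
  expect_equal(parse_age_label("<30 days")$upper_age, 30 / 365)
  lab <- parse_age_label("31 days <2")
  expect_equal(lab$lower_age, 31 / 365)
  expect_equal(lab$upper_age, 2)
  expect_equal(parse_age_label("7 years")$representative_age, 7)
  # en dash is accepted as a range separator
  expect_equal(parse_age_label("6–12 y")$representative_age, 9)
})

test_that("unparseable labels raise a parse error naming the text", {
  expect_error(parse_age_label("age not known"), class = "ade_parse_error")
  expect_error(parse_age_label("age not known"), "age not known")
  expect_error(parse_age_label(""), class = "ade_parse_error")
})

test_that("parse -> format -> parse round-trips the dataset's age labels", {
  obs <- load_observations(validate = FALSE)
  parseable <- !is.na(obs$representative_age) & is.na(obs$weight_kg) &
    obs$maturity == "not_applicable"
  labels <- unique(obs$age_label[parseable])
  expect_gt(length(labels), 30)
  for (lab in labels) {
    first <- parse_age_label(lab)
    again <- parse_age_label(format_age_label(first))
    expect_identical(first, again)
  }
})

test_that("stored representative ages agree with the label grammar", {
  obs <- load_observations(validate = FALSE)
  parseable <- !is.na(obs$representative_age) & is.na(obs$weight_kg) &
    obs$maturity == "not_applicable"
  for (i in which(parseable)) {
    expect_equal(parse_age_label(obs$age_label[i])$representative_age,
                 obs$representative_age[i], tolerance = 1e-3,
                 label = obs$age_label[i])
  }
})
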