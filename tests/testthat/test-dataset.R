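test_that("the packaged dataset matches its manifest", {
  obs <- load_observations()
  manifest <- validate_observations(obs)
  expect_equal(manifest$total_records, 75)
  expect_equal(as.integer(manifest$observations$monoclonal), 33)
  expect_equal(as.integer(manifest$observations$polyclonal), 21)
  expect_equal(as.integer(manifest$observations$non_antibody), 21)
  expect_equal(manifest$drugs$monoclonal, 13)
  expect_equal(manifest$drugs$polyclonal, 7)
  expect_equal(manifest$drugs$non_antibody, 9)
})

test_that("well-known rows carry their published values", {
  obs <- load_observations()
  toci <- obs[obs$drug_name == "Tocilizumab", ]
  expect_equal(nrow(toci), 1)
  expect_equal(toci$observed_clearance, 8.6)
  expect_equal(toci$reported_predicted_clearance, 7.9)
  expect_equal(toci$reported_percent_error, -8)
  expect_equal(toci$weight_kg, 20)
  expect_equal(toci$exponent_override, 0.75)
  sando <- obs[obs$drug_name == "Sandoglobulin", ]
  expect_equal(sando$maturity, "preterm")
  expect_equal(sando$reported_percent_error, -50)
  # both baseline series of the same product are retained
  expect_equal(sort(unique(obs$series[obs$drug_name == "Panzyga"])),
               c("baseline_corrected", "baseline_uncorrected"))
})

test_that("every row's recomputed percent error is within 5 points of the reported one", {
  obs <- load_observations(validate = FALSE)
  recomputed <- percent_error(obs$reported_predicted_clearance,
                              obs$observed_clearance)
  expect_true(all(abs(recomputed - obs$reported_percent_error) <= 5))
  # the largest drift comes from a boundary row recomputing to exactly 50
  drot <- obs$drug_name == "Drotrecogin alfa (activated)" &
    obs$age_label == "1-8 year"
  expect_equal(recomputed[drot], 50)
  expect_equal(obs$reported_percent_error[drot], 46)
})

test_that("validation rejects corrupted datasets and names the row", {
  obs <- load_observations()
  bad <- obs
  bad$observed_clearance[3] <- -1
  expect_error(validate_observations(bad), class = "ade_validation_error")
  expect_error(validate_observations(bad), bad$drug_name[3])
  drifted <- obs
  drifted$reported_percent_error[1] <- drifted$reported_percent_error[1] + 20
  expect_error(validate_observations(drifted),
               class = "ade_validation_error")
  expect_error(validate_observations(obs[0, ]),
               class = "ade_validation_error")
  expect_error(validate_observations(obs[1:10, ],
                                     expected = packaged_manifest <- list(
                                       total_records = 75,
                                       observations = list(monoclonal = 33),
                                       drugs = list(monoclonal = 13))),
               class = "ade_validation_error")
})

test_that("write -> read round-trips a dataset, preserving extra columns", {
  obs <- load_observations()
  obs$annotation <- paste0("note-", seq_len(nrow(obs)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(back$annotation, obs$annotation)
  expect_equal(back$drug_name, obs$drug_name)
  expect_equal(back$observed_clearance, obs$observed_clearance)
  expect_equal(back$representative_age, obs$representative_age)
})

test_that("re-serialising the packaged dataset is byte-identical", {
  src <- system.file("extdata", "pediatric_clearance.csv",
                     package = "adescale")
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(read_observations(src), path)
  expect_identical(readLines(path), readLines(src))
})

test_that("missing required columns and unicode minus are handled on read", {
  obs <- load_observations()
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs[, setdiff(names(obs), "observed_clearance")], path)
  expect_error(read_observations(path), class = "ade_schema_error")
  expect_error(read_observations(path), "observed_clearance")
  # unicode minus in a numeric column is normalised to ASCII
  tiny <- data.frame(
    drug_name = "x", drug_class = "monoclonal", adult_clearance = 10,
    clearance_units = "mL/h", observed_clearance = 5,
    reported_predicted_clearance = 4,
    reported_percent_error = "−20", stringsAsFactors = FALSE
  )
  write.csv(tiny, path, row.names = FALSE)
  expect_equal(read_observations(path)$reported_percent_error, -20)
})
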