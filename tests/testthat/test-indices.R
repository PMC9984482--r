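test_that("pulse pressure is the elementwise SBP-DBP difference", {
  expect_equal(pulse_pressure(154, 91), 63)
  expect_equal(pulse_pressure(c(150, 160, 140), c(90, 90, 90)),
               c(60, 70, 50))
  expect_error(pulse_pressure(120, 120), class = "ppv_invalid_reading")
  expect_error(pulse_pressure(numeric(0), numeric(0)),
               class = "ppv_empty_series")
  err <- tryCatch(pulse_pressure(c(150, 90, 140), c(90, 95, 80)),
                  error = identity)
  expect_s3_class(err, "ppv_invalid_reading")
  expect_equal(err$index, 2L)
})

test_that("derive_pulse_pressure appends pp and preserves order", {
  ws <- make_fixture("worked_series")
  out <- derive_pulse_pressure(ws)
  expect_s3_class(out, "tbl_df")
  expect_equal(out$pp, c(60, 70, 50, 60))
  expect_equal(out$time_offset_hours, ws$time_offset_hours)
})

test_that("sampling validation enforces count and gap rules", {
  full <- tibble::tibble(patient_id = "A",
                         time_offset_hours = seq(0, 72, by = 4),
                         sbp = 150, dbp = 90)
  v <- validate_sampling(full)
  expect_true(v$accepted)
  expect_true(is.na(v$reason))

  sparse <- tibble::tibble(patient_id = "B",
                           time_offset_hours = seq(0, 72, length.out = 10),
                           sbp = 150, dbp = 90)
  v <- validate_sampling(sparse)
  expect_false(v$accepted)
  expect_equal(v$reason, "too_few_readings")

  # enough readings, but a 12-h interruption in the 4-h schedule
  gappy <- tibble::tibble(patient_id = "C",
                          time_offset_hours = setdiff(seq(0, 72, 4),
                                                      c(28, 32)),
                          sbp = 150, dbp = 90)
  v <- validate_sampling(gappy)
  expect_equal(v$n_readings, 17)
  expect_equal(v$reason, "gap_too_large")

  # count failure takes precedence over gap failure
  both <- tibble::tibble(patient_id = "D",
                         time_offset_hours = c(0, 24, 48, 72),
                         sbp = 150, dbp = 90)
  expect_equal(validate_sampling(both)$reason, "too_few_readings")
})

test_that("policy thresholds are configurable and validated", {
  sparse <- tibble::tibble(patient_id = "B",
                           time_offset_hours = seq(0, 72, length.out = 10),
                           sbp = 150, dbp = 90)
  lax <- sampling_policy(min_fraction = 0.5, max_gap_hours = 10)
  expect_true(validate_sampling(sparse, lax)$accepted)
  expect_error(sampling_policy(min_fraction = 0), class = "ppv_bad_policy")
  expect_error(sampling_policy(max_gap_hours = 2), class = "ppv_bad_policy")
})

test_that("summarize_ppv reproduces hand-computed worked examples", {
  flat <- summarize_ppv(c(60, 60, 60, 60))
  expect_equal(unlist(flat[c("mean_pp", "sd", "cv", "sv", "arv",
                             "dmm", "msc")]),
               c(mean_pp = 60, sd = 0, cv = 0, sv = 0, arv = 0,
                 dmm = 0, msc = 0))

  worked <- summarize_ppv(c(60, 70, 50, 60))
  expect_equal(worked$mean_pp, 60)
  expect_equal(worked$sd, sqrt(200 / 3))
  expect_equal(worked$cv, 100 * sqrt(200 / 3) / 60)
  expect_equal(worked$sv, sqrt(600 / 3))
  expect_equal(worked$arv, 40 / 3)
  expect_equal(worked$dmm, 20)
  expect_equal(worked$msc, 20)

  # n = 2 closed form: sd = |b-a|/sqrt(2), sv = arv = msc = dmm = |b-a|
  two <- summarize_ppv(c(50, 71))
  expect_equal(two$sd, 21 / sqrt(2))
  expect_equal(two$sv, 21)
  expect_equal(two$arv, 21)
  expect_equal(two$msc, 21)
  expect_equal(two$dmm, 21)

  expect_error(summarize_ppv(60), class = "ppv_too_short")
  expect_true(is.nan(summarize_ppv(c(0, 0))$cv))
})

test_that("summaries obey translation, scaling and reversal symmetries", {
  withr::with_seed(42, {
    for (i in 1:50) {
      pp <- random_pp_series()
      base <- summarize_ppv(pp)
      shifted <- summarize_ppv(pp + 7.5)
      dispersion <- c("sd", "sv", "arv", "dmm", "msc")
      expect_equal(shifted[dispersion], base[dispersion])
      expect_equal(shifted$mean_pp, base$mean_pp + 7.5)

      scaled <- summarize_ppv(pp * 1.3)
      expect_equal(unlist(scaled[c("mean_pp", dispersion)]),
                   1.3 * unlist(base[c("mean_pp", dispersion)]))
      expect_equal(scaled$cv, base$cv)

      expect_equal(summarize_ppv(rev(pp)), base)
    }
  })
})

test_that("dispersion orderings hold on random series", {
  withr::with_seed(7, {
    for (i in 1:200) {
      s <- summarize_ppv(random_pp_series())
      expect_lte(s$arv, s$sv + 1e-12)
      expect_lte(s$arv, s$msc + 1e-12)
      expect_lte(s$msc, s$dmm + 1e-12)
      expect_lte(s$sd, s$dmm + 1e-12)
    }
  })
})

test_that("ppv_indices summarises accepted series and flags the rest", {
  readings <- dplyr::bind_rows(
    make_fixture("worked_series"),
    tibble::tibble(patient_id = "FULL",
                   time_offset_hours = seq(0, 72, 4),
                   sbp = 150 + sin(0:18), dbp = 90)
  )
  idx <- ppv_indices(readings)
  expect_equal(nrow(idx), 2)
  w <- idx[idx$patient_id == "W001", ]
  expect_false(w$accepted)
  expect_equal(w$reason, "too_few_readings")
  expect_true(is.na(w$sd))
  f <- idx[idx$patient_id == "FULL", ]
  expect_true(f$accepted)
  expect_equal(f$mean_pp, mean(60 + sin(0:18)))

  # without a policy, any series of length >= 2 is summarised
  idx2 <- ppv_indices(readings, policy = NULL)
  expect_equal(idx2$sd[idx2$patient_id == "W001"], sqrt(200 / 3))
})

test_that("readings CSV round-trips, sorts on load, rejects tied times", {
  path <- withr::local_tempfile(fileext = ".csv")
  ws <- make_fixture("worked_series")
  readr::write_csv(ws[c(3, 1, 4, 2), ], path)
  loaded <- read_bp_readings(path)
  expect_equal(loaded$time_offset_hours, ws$time_offset_hours)
  expect_equal(loaded$sbp, ws$sbp)

  dup <- ws
  dup$time_offset_hours[2] <- 0
  readr::write_csv(dup, path)
  expect_error(read_bp_readings(path), class = "ppv_bad_input")
})
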