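test_that("entrance calibration factor is the chamber/film ratio", {
  expect_equal(entrance_calibration_factor(100, 100), 1.0)
  expect_equal(entrance_calibration_factor(100, 50), 2.0)
  expect_equal(entrance_calibration_factor(200, 48.38), 4.134, tolerance = 1e-3)
  expect_error(entrance_calibration_factor(200, 0),
               class = "filmdose_division_error")
})

test_that("entrance dose chains film dose, factor and CF product", {
  expect_equal(entrance_dose(123.4, 1, 1), 123.4)
  d <- entrance_dose(47.712875, 4.134, 1)
  expect_equal(d, 197.245, tolerance = 1e-4)
  expect_equal(100 * abs(d - 200) / 200, 1.38, tolerance = 0.01)
  expect_equal(entrance_dose(48.38, 4.134, 1), 200, tolerance = 0.1)
})

test_that("dose at depth follows the interpolated PDD", {
  tab <- pdd_table(c(0.5, 5, 10), c(100, 82.3, 50))
  expect_equal(dose_at_depth(200, tab, 0.5), 200)
  expect_equal(dose_at_depth(200, tab, 10), 100)
  expect_equal(dose_at_depth(200, tab, 7.5), 200 * (82.3 + 50) / 2 / 100)
  expect_error(dose_at_depth(200, tab, 12), class = "filmdose_range_error")
})

test_that("dose_at_depth is non-increasing beyond dmax for falling PDD", {
  tab <- read_pdd_table(system.file("extdata", "pdd_co60_synthetic.csv",
                                    package = "filmdose"))
  depths <- seq(0.5, 20, length.out = 60)
  doses <- vapply(depths, function(z) dose_at_depth(200, tab, z), numeric(1))
  expect_true(all(diff(doses) <= 0))
})

test_that("PDD tables are validated at construction", {
  expect_error(pdd_table(c(0.5, 5), c(99, 80)),
               class = "filmdose_invalid_argument")  # no 100 at dmax
  expect_error(pdd_table(c(5, 0.5), c(80, 100)),
               class = "filmdose_invalid_argument")  # unsorted
})

test_that("OD extrapolation to the skin reference depth matches the worked case", {
  ext <- extrapolate_od_to_depth(0.080, 0.03, 0.935, 0.08, 0.070)
  expect_equal(ext$od_raw, 0.0294152, tolerance = 1e-4)
  expect_identical(ext$od_rounded, 0.03)
  # interpolation endpoint and midpoint identities
  expect_equal(extrapolate_od_to_depth(0.080, 0.03, 0.935, 0.08, 0.080)$od_raw,
               0.03)
  expect_equal(extrapolate_od_to_depth(1, 0.05, 3, 0.09, 2)$od_raw, 0.07)
  expect_error(extrapolate_od_to_depth(0.5, 0.03, 0.5, 0.08, 0.070),
               class = "filmdose_degenerate_geometry")
})

test_that("skin calibration factor is 1.00 on rounded ODs, 0.979 raw", {
  cal <- printed_curve()
  expect_equal(skin_calibration_factor(0.0294152, 0.03, cal), 1.00)
  expect_equal(skin_calibration_factor(0.07, 0.07, cal, round_od = FALSE), 1.0)
  expect_equal(skin_calibration_factor(0.0294152, 0.03, cal, round_od = FALSE),
               0.979, tolerance = 1e-3)
})

test_that("skin dose and its percent of prescription match the worked values", {
  cal <- printed_curve()
  df_unenc <- od_to_dose(cal, 0.05)
  df_enc <- od_to_dose(cal, 0.14)
  expect_equal(skin_dose(df_enc, 1.00), 139.4528, tolerance = 1e-4)
  expect_equal(round(100 * skin_dose(df_enc, 1.00) / 200), 70)
  expect_equal(round(100 * skin_dose(df_unenc, 1.00) / 200), 24)
  expect_equal(skin_dose(5, 1), 5)
})

test_that("percent skin dose reduces to the calibration-factor ratio", {
  expect_equal(percent_skin_dose(4.134, 1, 1), 24.19, tolerance = 1e-3)
  expect_equal(round(percent_skin_dose(4.134, 1, 1)), 24)
  expect_equal(percent_skin_dose(1, 1, 1), 100)
  expect_equal(percent_skin_dose(4.134, 2, 1), 12.10, tolerance = 1e-3)
})

test_that("percent skin dose, entrance dose and skin dose are algebraically consistent", {
  withr::with_seed(11, {
    for (i in 1:25) {
      df <- runif(1, 10, 300)
      fc <- runif(1, 1, 6)
      pc <- runif(1, 0.7, 1.4)
      lhs <- percent_skin_dose(fc, pc, 1) * entrance_dose(df, fc, pc) / 100
      expect_equal(lhs, skin_dose(df, 1), tolerance = 1e-9)
    }
  })
})
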