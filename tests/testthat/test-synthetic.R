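test_that("identical seeds reproduce every dataset byte-for-byte", {
  sc <- function() response_scenario(noise_sd_od = 0.003, seed = 99)
  expect_identical(generate_calibration_dataset(sc()),
                   generate_calibration_dataset(sc()))
  expect_identical(generate_cf_landscape(sc()), generate_cf_landscape(sc()))
  sweep <- default_condition_sweep()
  expect_identical(simulate_treatment_readings(sc(), sweep),
                   simulate_treatment_readings(sc(), sweep))
  sc2 <- response_scenario(noise_sd_od = 0.003, seed = 100)
  expect_false(identical(generate_calibration_dataset(sc()),
                         generate_calibration_dataset(sc2)))
})

test_that("growth series saturate at the calibrated plateau", {
  cal <- ebt2_co60_curve()
  g <- generate_growth_series(200, times = seq(60, 6480, by = 60))
  plateau <- dose_to_od(cal, 200)
  expect_lt(abs(tail(g$od, 1) - plateau), 0.01 + 1e-12)
  g50 <- generate_growth_series(50, quantize = FALSE)
  g800 <- generate_growth_series(800, quantize = FALSE)
  expect_gt(tail(g800$od, 1), tail(g50$od, 1))
  # noiseless, unquantized saturation is non-decreasing everywhere
  expect_true(all(diff(g800$od) >= 0))
  expect_error(generate_growth_series(200, times = c(60, 30)),
               class = "filmdose_input_error")
})

test_that("default growth series stabilize within 24 hours", {
  g <- generate_growth_series(200, times = seq(60, 6480, by = 60), seed = 5)
  expect_lte(stabilization_time(g$od, g$time_min), 1440)
  g800 <- generate_growth_series(800, times = seq(60, 6480, by = 60), seed = 5)
  expect_lte(stabilization_time(g800$od, g800$time_min), 1440)
  # low doses stabilize no later than high doses
  g50 <- generate_growth_series(50, times = seq(60, 6480, by = 60), seed = 5)
  expect_lte(stabilization_time(g50$od, g50$time_min),
             stabilization_time(g800$od, g800$time_min))
})

test_that("stabilization detection handles constant and drifting series", {
  times <- seq(60, 600, by = 60)
  expect_equal(stabilization_time(rep(0.2, 10), times), 60)
  drifting <- 0.1 + 0.02 * seq_len(10)
  expect_true(is.na(stabilization_time(drifting, times)))
})

test_that("noiseless calibration datasets close the loop with the fit", {
  sc <- response_scenario(seed = 3)
  pts <- generate_calibration_dataset(sc, doses_cGy = seq(50, 800, length.out = 12))
  fit <- fit_calibration(pts)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_equal(est, printed_coefs, tolerance = 1e-6)
  empty <- generate_calibration_dataset(sc, doses_cGy = numeric(0))
  expect_equal(nrow(empty), 0)
  expect_error(generate_calibration_dataset(sc, doses_cGy = 5000),
               class = "filmdose_range_error")
})

test_that("noisy refit of the ten-dose schedule stays tightly correlated", {
  sc <- response_scenario(noise_sd_od = 0.005, seed = 21)
  fit <- fit_calibration(generate_calibration_dataset(sc, calibration_doses))
  expect_gt(glance(fit)$r_fit, 0.995)
})

test_that("landscape trends: contamination inflates the bare film only", {
  sc <- response_scenario(seed = 8)  # noiseless
  nd <- normalized_response(generate_cf_landscape(sc))
  ref <- reference_conditions()
  # reference condition of every series is exactly 1
  refs <- nd |>
    dplyr::group_by(parameter, encapsulated) |>
    dplyr::summarise(
      at_ref = normalized_response[abs(value - ref[unique(parameter)]) < 1e-9],
      .groups = "drop")
  expect_equal(refs$at_ref, rep(1, nrow(refs)))
  pick <- function(p, enc) dplyr::filter(nd, parameter == p, encapsulated == enc)
  expect_true(all(diff(pick("field_size_cm", FALSE)$normalized_response) > 0))
  expect_true(all(diff(pick("gantry_deg", FALSE)$normalized_response) > 0))
  expect_true(all(diff(pick("ssd_cm", FALSE)$normalized_response) < 0))
  expect_true(all(diff(pick("wedge_deg", FALSE)$normalized_response) < 0))
  # encapsulated film: flat in field size and gantry angle (within 1%)
  for (p in c("field_size_cm", "gantry_deg")) {
    enc <- pick(p, TRUE)$normalized_response
    expect_lt(max(abs(enc - 1)), 0.01)
  }
})

test_that("correction factors estimated from the landscape recover truth", {
  sc <- response_scenario(noise_sd_od = 0.001, seed = 13)
  est <- estimate_cf_set(generate_cf_landscape(sc))
  truth <- default_cf_truth(FALSE)
  for (p in names(truth)) {
    rel <- abs(est[[p]]$knots$cf - truth[[p]]$knots$cf) / truth[[p]]$knots$cf
    expect_lt(max(rel), 0.01)
  }
})

test_that("treatment simulation closes the pipeline loop when noiseless", {
  sc <- response_scenario(seed = 2)
  sim <- simulate_treatment_readings(
    sc, tibble::tibble(field_size_cm = NA_real_), prescribed_cGy = 200)
  cfs <- estimate_cf_set(generate_cf_landscape(sc))
  rep <- run_pipeline(sim$readings, sc$true_curve, cfs,
                      run_config(200, sc$fcal_entrance))
  expect_equal(rep$d_entrance_cGy, 200, tolerance = 0.1 / 200)
  expect_error(
    simulate_treatment_readings(sc, tibble::tibble(collimator = 5)),
    class = "filmdose_lookup_error")
})

test_that("simulated entrance doses stay within 3% across mixed conditions", {
  sc <- response_scenario(noise_sd_od = 0.001, seed = 17)
  sim <- simulate_treatment_readings(sc, default_condition_sweep(), 200)
  cfs <- estimate_cf_set(generate_cf_landscape(sc))
  rep <- run_pipeline(sim$readings, sc$true_curve, cfs,
                      run_config(200, sc$fcal_entrance))
  expect_lte(max(rep$percent_deviation_raw), 3)
})
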