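test_that("net optical density is the post-minus-pre difference", {
  expect_equal(net_optical_density(0.00, 0.14), 0.14)
  expect_equal(net_optical_density(0.05, 0.05), 0.00)
  expect_equal(net_optical_density(0.03, 0.08), 0.05)
  expect_equal(net_optical_density(c(0, 0.03), c(0.14, 0.08)), c(0.14, 0.05))
})

test_that("negative readings error, negative NOD warns but passes through", {
  expect_error(net_optical_density(-0.01, 0.1), class = "filmdose_invalid_reading")
  expect_error(net_optical_density(0.1, -0.1), class = "filmdose_invalid_reading")
  expect_warning(nod <- net_optical_density(0.08, 0.05),
                 class = "filmdose_negative_nod")
  expect_equal(nod, -0.03)
})

test_that("add_net_od appends nod and enforces its schema", {
  readings <- tibble::tibble(film_id = c("a", "b"),
                             od_pre = c(0, 0.03), od_post = c(0.14, 0.08))
  out <- add_net_od(readings)
  expect_equal(out$nod, c(0.14, 0.05))
  expect_error(add_net_od(readings[, c("film_id", "od_pre")]),
               class = "filmdose_schema_error")
})

test_that("least squares through noiseless cubic points recovers it exactly", {
  fit <- fit_calibration(noiseless_points())
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_equal(est, printed_coefs, tolerance = 1e-6)
  expect_equal(glance(fit)$r_fit, 1.0, tolerance = 1e-9)
  expect_equal(fit$od_domain, c(0.05, 0.60))
})

test_that("coefficients are recovered within 3 sd under dose noise", {
  pts <- noiseless_points()
  withr::with_seed(101, pts$dose_cGy <- pts$dose_cGy + rnorm(nrow(pts), 0, 2))
  fit <- fit_calibration(pts)
  td <- tidy(fit)
  expect_true(all(abs(td$estimate - printed_coefs[td$term]) <= 3 * td$std.error))
})

test_that("rank-deficient or non-monotone calibrations are refused", {
  few <- noiseless_points(4)
  expect_error(fit_calibration(few), class = "filmdose_fit_error")
  degenerate <- tibble::tibble(nod = rep(c(0.1, 0.2, 0.3), c(3, 3, 3)),
                               dose_cGy = rep(c(100, 200, 300), c(3, 3, 3)))
  expect_error(fit_calibration(degenerate), class = "filmdose_fit_error")
  # a decreasing relation cannot give an increasing cubic
  decr <- tibble::tibble(nod = seq(0.1, 0.5, length.out = 8),
                         dose_cGy = seq(500, 100, length.out = 8))
  expect_error(fit_calibration(decr), class = "filmdose_monotonicity_error")
})

test_that("od_to_dose evaluates the printed cubic", {
  cal <- printed_curve()
  expect_equal(od_to_dose(cal, 0), -2.328)
  expect_equal(od_to_dose(cal, 0.05), 47.712875, tolerance = 1e-9)
  expect_equal(od_to_dose(cal, 0.14), 139.4528, tolerance = 1e-9)
})

test_that("domain strictness and negative-dose clamping are explicit", {
  cal <- printed_curve()
  expect_error(od_to_dose(cal, 0.9), class = "filmdose_domain_error")
  expect_equal(od_to_dose(cal, 0.9, strict = FALSE),
               1685 * 0.9^3 - 187.9 * 0.81 + 1006 * 0.9 - 2.328)
  expect_warning(d <- od_to_dose(cal, 0, clamp = TRUE),
                 class = "filmdose_negative_dose")
  expect_equal(d, 0)
})

test_that("dose_to_od inverts the curve", {
  cal <- printed_curve()
  expect_equal(dose_to_od(cal, -2.328), 0.0)
  expect_equal(dose_to_od(cal, 47.712875), 0.05, tolerance = 1e-6)
  expect_equal(dose_to_od(cal, od_to_dose(cal, 0.20)), 0.20, tolerance = 1e-7)
  expect_error(dose_to_od(cal, 5000), class = "filmdose_range_error")
})

test_that("round trip holds across the whole OD domain", {
  cal <- printed_curve()
  ods <- seq(cal$od_domain[1], cal$od_domain[2], length.out = 100)
  back <- dose_to_od(cal, od_to_dose(cal, ods))
  expect_lt(max(abs(back - ods)), 1e-6)
})

test_that("any noiseless monotone cubic is reproduced by the fit", {
  cubics <- list(c(a = 500, b = 20, c = 300, d = 5),
                 c(a = 1200, b = -100, c = 800, d = 0),
                 c(a = 0.5, b = 0.1, c = 50, d = -1))
  for (k in cubics) {
    nod <- seq(0.02, 0.5, length.out = 9)
    pts <- tibble::tibble(
      nod = nod,
      dose_cGy = k[["a"]] * nod^3 + k[["b"]] * nod^2 + k[["c"]] * nod + k[["d"]])
    est <- setNames(tidy(fit_calibration(pts))$estimate, c("a", "b", "c", "d"))
    expect_equal(est, k, tolerance = 1e-6)
  }
})

test_that("the calibration is strictly increasing on its domain", {
  cal <- printed_curve()
  grid <- seq(cal$od_domain[1], cal$od_domain[2], length.out = 1000)
  expect_true(all(diff(od_to_dose(cal, grid)) > 0))
})

test_that("curve construction validates its domain and monotonicity", {
  expect_error(calibration_curve(1, 1, 1, 0, od_domain = c(-0.1, 0.5)),
               class = "filmdose_invalid_argument")
  # dose falling in OD: rejected at construction
  expect_error(calibration_curve(0, 0, -10, 100, od_domain = c(0, 1)),
               class = "filmdose_monotonicity_error")
})
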