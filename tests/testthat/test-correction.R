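test_that("correction factor normalizes chamber/film ratios", {
  expect_equal(correction_factor(200, 48.38, 200, 48.38), 1.0)
  expect_equal(correction_factor(200, 96.76, 200, 48.38), 0.5)
  expect_equal(correction_factor(190, 48.38, 200, 48.38), 0.95)
  expect_error(correction_factor(200, 0, 200, 48.38),
               class = "filmdose_division_error")
})

test_that("CF tables built from paired readings have CF = 1 at reference", {
  m <- tibble::tibble(value = c(4, 10, 16, 24),
                      ric_cGy = c(200, 200, 200, 200),
                      rf_cGy = c(46, 48.38, 51, 55))
  tab <- build_cf_table(m, "field_size_cm", reference_value = 10)
  iref <- which(tab$knots$value == 10)
  expect_identical(tab$knots$cf[iref], 1.0)
  expect_true(all(tab$knots$cf > 0))
})

test_that("CF tables are invariant to rescaling all chamber readings", {
  m <- tibble::tibble(value = c(75, 100, 120),
                      ric_cGy = c(355, 200, 139),
                      rf_cGy = c(90, 48.38, 33))
  t1 <- build_cf_table(m, "ssd_cm", reference_value = 100)
  m2 <- dplyr::mutate(m, ric_cGy = ric_cGy * 3.7)
  t2 <- build_cf_table(m2, "ssd_cm", reference_value = 100)
  expect_equal(t1$knots$cf, t2$knots$cf)
})

test_that("lookup interpolates linearly and refuses to extrapolate", {
  tab <- cf_table("field_size_cm", c(10, 20, 24), c(1.0, 0.90, 0.86), 10)
  expect_identical(lookup_cf(tab, 20), 0.90)
  expect_equal(lookup_cf(tab, 15), 0.95)
  expect_error(lookup_cf(tab, 25), class = "filmdose_extrapolation_error")
  expect_error(lookup_cf(tab, 5), class = "filmdose_extrapolation_error")
})

test_that("cf_table construction enforces the reference knot", {
  expect_error(cf_table("ssd_cm", c(80, 120), c(0.98, 1.02), 100),
               class = "filmdose_invalid_argument")
  expect_error(cf_table("ssd_cm", c(80, 100), c(0.98, 1.01), 100),
               class = "filmdose_invalid_argument")
})

test_that("product of correction factors multiplies per-parameter lookups", {
  set <- cf_set(
    cf_table("field_size_cm", c(10, 20), c(1.0, 0.98), 10),
    cf_table("ssd_cm", c(80, 100, 120), c(0.97, 1.0, 1.05), 100)
  )
  expect_identical(product_cf(set), 1)
  expect_equal(product_cf(set, list(field_size_cm = 20, ssd_cm = 120)),
               0.98 * 1.05, tolerance = 1e-12)
  expect_equal(product_cf(set, list(field_size_cm = 10, ssd_cm = 100)), 1.0,
               tolerance = 1e-9)
  expect_error(product_cf(set, list(gantry_deg = 30)),
               class = "filmdose_lookup_error")
})

test_that("product_cf is permutation-invariant in its conditions", {
  set <- cf_set(
    cf_table("field_size_cm", c(4, 10, 24), c(1.06, 1.0, 0.88), 10),
    cf_table("ssd_cm", c(75, 100, 120), c(0.96, 1.0, 1.04), 100),
    cf_table("gantry_deg", c(0, 45, 90), c(1.0, 0.95, 0.89), 0)
  )
  conds <- list(field_size_cm = 17, ssd_cm = 83, gantry_deg = 60)
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  vals <- vapply(perms, function(p) product_cf(set, conds[p]), numeric(1))
  expect_equal(vals, rep(vals[1], 3))
})

test_that("paired comparison: identical series give p = 1, difference 0", {
  x <- c(1.00, 1.02, 0.98, 1.05, 0.97, 1.01, 0.99, 1.03, 1.00, 0.96, 1.04)
  out <- compare_configurations(x, x)
  expect_equal(out$p_value, 1.0)
  expect_equal(out$mean_difference, 0)
  expect_false(out$significant)
  expect_equal(out$n, 11L)
})

test_that("a large standardized shift is detected with high power", {
  base <- seq(0.95, 1.15, length.out = 11)
  shifted <- withr::with_seed(7, base + 0.5 + rnorm(11, 0, 0.01))
  out <- compare_configurations(shifted, base)
  expect_lt(out$p_value, 0.001)
  expect_true(out$significant)
})

test_that("degenerate and undersized comparisons are handled", {
  expect_error(compare_configurations(c(1, 2), c(1, 2)),
               class = "filmdose_insufficient_data")
  expect_error(compare_configurations(1:5, 1:4),
               class = "filmdose_shape_error")
  # constant shift with zero within-pair variance: decisive, not an error
  out <- compare_configurations(c(1, 2, 3) + 0.5, c(1, 2, 3))
  expect_equal(out$p_value, 0)
  expect_true(out$significant)
})
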