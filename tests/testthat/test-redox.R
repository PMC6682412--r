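# Ratiometric roGFP math: ratio, OxD, its inverse, dynamic range,
# calibration handling and the out-of-range policies.

test_that("compute_ratio divides, guards the i488 floor, never returns 0 silently", {
  expect_equal(compute_ratio(2.0, 1.0), 2.0)
  expect_equal(compute_ratio(0, 5.0), 0.0)
  expect_error(compute_ratio(1.0, 0), "undefined ratio")
  r <- compute_ratio(c(1, 1), c(0, 2), on_invalid = "na")
  expect_true(is.na(r[1]))
  expect_equal(r[2], 0.5)
  expect_true(compute_ratio(3, 2) > compute_ratio(2.5, 2))  # monotone in i405
})

test_that("compute_oxd matches the hand-evaluated calibrated form", {
  calib <- calibration_set(R_red = 1.0, R_ox = 5.0, i488_red = 1.0,
                           i488_ox = 0.5)
  # (3-1) / (0.5*(5-3) + (3-1)) = 2/3
  expect_equal(compute_oxd(3.0, calib)$value, 2 / 3, tolerance = 1e-12)
})

test_that("OxD anchors are exact and the map is monotone for random calibrations", {
  set.seed(42)
  for (i in 1:50) {
    calib <- random_calibration()
    expect_identical(compute_oxd(calib$R_red, calib)$value, 0)
    expect_equal(compute_oxd(calib$R_ox, calib)$value, 1, tolerance = 1e-15)
    R <- sort(runif(20, calib$R_red, calib$R_ox))
    v <- compute_oxd(R, calib)$value
    expect_true(all(diff(v) > 0))
  }
})

test_that("ratio <-> OxD round-trips to 1e-12 on [R_red, R_ox]", {
  set.seed(7)
  for (i in 1:25) {
    calib <- random_calibration()
    x <- runif(50)
    R <- oxd_to_ratio(x, calib)
    expect_true(all(R >= calib$R_red - 1e-12 & R <= calib$R_ox + 1e-12))
    expect_equal(compute_oxd(R, calib)$value, x, tolerance = 1e-12)
    R2 <- runif(50, calib$R_red, calib$R_ox)
    expect_equal(oxd_to_ratio(compute_oxd(R2, calib)$value, calib), R2,
                 tolerance = 1e-12)
  }
  expect_error(oxd_to_ratio(-0.1, random_calibration()), "0, 1")
  calib <- random_calibration()
  expect_equal(oxd_to_ratio(0, calib), calib$R_red)
  expect_equal(oxd_to_ratio(1, calib), calib$R_ox)
})

test_that("equal reference i488 collapses OxD to the linear form", {
  calib <- calibration_set(R_red = 1.2, R_ox = 4.8, i488_red = 0.9,
                           i488_ox = 0.9)
  R <- seq(1.2, 4.8, length.out = 11)
  expect_equal(compute_oxd(R, calib)$value,
               (R - calib$R_red) / (calib$R_ox - calib$R_red),
               tolerance = 1e-12)
})

test_that("over-range policy: (1, 1.10] kept with flag, > 1.10 excluded", {
  calib <- calibration_set(1, 5, i488_red = 1, i488_ox = 1)
  # linear form: OxD = (R-1)/4 -> R = 1 + 4*oxd
  r_over <- 1 + 4 * 1.05
  r_excl <- 1 + 4 * 1.2
  res <- compute_oxd(c(3, r_over, r_excl, NA), calib)
  expect_equal(res$flag, c("in_range", "over_range", "excluded", "invalid"))
  expect_equal(res$value[2], 1.05, tolerance = 1e-12)
  expect_equal(res$value[3], 1.2, tolerance = 1e-12)  # retained but flagged
  # non-positive denominator: R far above R_ox with i488 quotient > 1
  calib2 <- calibration_set(1, 5, i488_red = 1, i488_ox = 2)
  res2 <- compute_oxd(30, calib2)
  expect_equal(res2$flag, "excluded")
  expect_true(is.na(res2$value))
})

test_that("dynamic range is R_ox/R_red and invariants reject degenerate sets", {
  expect_equal(dynamic_range(calibration_set(1.0, 5.57, 1, 0.5)), 5.57)
  expect_equal(dynamic_range(calibration_set(2.0, 7.0, 1, 0.5)), 3.5)
  expect_error(calibration_set(2.0, 2.0, 1, 1))   # R_ox must exceed R_red
  expect_error(calibration_set(-1, 5, 1, 1))
  expect_error(calibration_set(1, 5, 0, 1))
})

test_that("calibration estimation aggregates by median or mean and files round-trip", {
  set.seed(1)
  red <- rnorm(500, 1.0, 0.05); ox <- rnorm(500, 5.5, 0.2)
  c_med <- estimate_calibration(red, ox, rnorm(500, 2, .1), rnorm(500, 1, .1))
  c_mean <- estimate_calibration(red, ox, rnorm(500, 2, .1), rnorm(500, 1, .1),
                                 aggregate = "mean")
  expect_equal(c_med$R_red, median(red))
  expect_equal(c_mean$R_red, mean(red))
  path <- tempfile(fileext = ".yaml")
  write_calibration(c_med, path)
  back <- read_calibration(path)
  expect_equal(back$R_red, c_med$R_red)
  expect_equal(back$R_ox, c_med$R_ox)
  expect_equal(back$i488_red, c_med$i488_red)
  expect_equal(back$i488_ox, c_med$i488_ox)
  expect_error(read_calibration(tempfile()), "not found")
})
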