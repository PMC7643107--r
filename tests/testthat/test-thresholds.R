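test_that("characteristic lengths of TM1-TM4", {
  ch <- ref_channel()
  D <- hydraulic_diameter(ch)
  expect_equal(characteristic_length("TM1", ch), D)
  expect_equal(characteristic_length("TM2", ch), um(220))
  expect_equal(characteristic_length("TM3", ch) * 1e6, 241.3889,
               tolerance = 1e-6)
  expect_equal(characteristic_length("TM4", ch), D)
  expect_error(characteristic_length("TM9", ch), "unknown")
})

test_that("threshold diameters on the reference channel", {
  ch <- ref_channel()
  expect_equal(round_threshold_um(threshold_diameter("TM1", ch)), 21)
  expect_equal(threshold_diameter("TM1", ch) * 1e6, 21.38889,
               tolerance = 1e-6)
  expect_equal(round_threshold_um(threshold_diameter("TM2", ch)), 15)
  expect_equal(threshold_diameter("TM2", ch) * 1e6, 15.4)
  c_talc <- density_coefficient(2.75)
  expect_equal(round_threshold_um(threshold_diameter("TM4", ch, c_talc)), 26)
  expect_error(threshold_diameter("TM4", ch, c = 0.9), "c >= 1")
  # TM4 at c = 1 is exactly TM1
  expect_identical(threshold_diameter("TM4", ch, 1),
                   threshold_diameter("TM1", ch))
})

test_that("half-micron reporting reproduces intermediate-density thresholds", {
  ch <- ref_channel()
  # PET-like 1.38 g/ml -> 22.5 um; PA-like 1.15 g/ml -> 21.5 um
  t_pet <- threshold_diameter("TM4", ch, density_coefficient(1.38))
  expect_equal(round_threshold_um(t_pet, granularity = 0.5), 22.5)
  t_pa <- threshold_diameter("TM4", ch, density_coefficient(1.15))
  expect_equal(round_threshold_um(t_pa, granularity = 0.5), 21.5)
})

test_that("density coefficient: published line, clamping, unit guard", {
  expect_equal(density_coefficient(1.38), 1.04226, tolerance = 1e-6)
  expect_equal(density_coefficient(1.15), 1.01305, tolerance = 1e-6)
  expect_equal(density_coefficient(1.05), 1.00035, tolerance = 1e-6)
  # below the c = 1 crossing the floor engages (with an extrapolation warning)
  expect_warning(c_low <- density_coefficient(1.0), "outside")
  expect_identical(c_low, 1)
  expect_error(density_coefficient(-1), "positive")
  expect_error(density_coefficient(1050), "g/ml")
  # non-decreasing in density
  rho <- seq(1.05, 2.75, length.out = 30)
  expect_true(all(diff(density_coefficient(rho)) >= 0))
})

test_that("two-anchor calibration reproduces the published coefficients", {
  ch <- ref_channel()
  c_talc <- coefficient_from_threshold(um(26), ch)
  expect_equal(c_talc, 1.215584, tolerance = 1e-6)
  m <- calibrate_density_model(c(1.05, 2.75), c(1, c_talc))
  expect_equal(round(m$slope, 3), 0.127)
  expect_equal(round(m$intercept, 3), 0.867)
  expect_equal(m$valid_range, c(1.05, 2.75))
  # exact interpolation at the anchors
  expect_equal(density_coefficient(1.05, m), 1, tolerance = 1e-12)
  expect_equal(density_coefficient(2.75, m), c_talc, tolerance = 1e-12)
})

test_that("calibration handles flat, collinear and invalid anchor sets", {
  flat <- calibrate_density_model(c(1, 2), c(1, 1))
  expect_equal(flat$slope, 0)
  expect_equal(flat$intercept, 1)
  three <- calibrate_density_model(c(1, 1.5, 2), c(1, 1.25, 1.5))
  two <- calibrate_density_model(c(1, 2), c(1, 1.5))
  expect_equal(three$slope, two$slope, tolerance = 1e-12)
  expect_equal(three$intercept, two$intercept, tolerance = 1e-12)
  expect_error(calibrate_density_model(1.05, 1), "anchor")
  expect_error(calibrate_density_model(c(1, 1), c(1, 1.2)), "distinct")
})

test_that("coefficient_from_threshold and TM4 are exact inverses", {
  ch <- ref_channel()
  D <- hydraulic_diameter(ch)
  expect_equal(coefficient_from_threshold(0.07 * D, ch), 1,
               tolerance = 1e-12)
  set.seed(13)
  for (a in runif(10, 21.4, 60) * 1e-6) {
    c_val <- coefficient_from_threshold(a, ch)
    expect_equal(threshold_diameter("TM4", ch, c_val), a,
                 tolerance = 1e-12)
  }
})

test_that("threshold ordering TM2 <= TM3 <= TM1 for wide channels", {
  set.seed(17)
  for (i in 1:25) {
    h <- runif(1, 50, 400) * 1e-6
    w <- h * runif(1, 1.05, 6)
    ch <- rect_channel(w, h, mm(5))
    t1 <- threshold_diameter("TM1", ch)
    t2 <- threshold_diameter("TM2", ch)
    t3 <- threshold_diameter("TM3", ch)
    expect_lte(t2, t3)
    expect_lte(t3, t1)
  }
  # TM4 monotone in density
  ch <- ref_channel()
  ts <- vapply(seq(1.05, 2.75, length.out = 20), function(rho) {
    threshold_diameter("TM4", ch, density_coefficient(rho))
  }, numeric(1))
  expect_true(all(diff(ts) >= 0))
})

test_that("is_focused classifies around the thresholds", {
  ch <- ref_channel()
  expect_false(is_focused(um(21), "TM1", ch))
  expect_true(is_focused(um(21.5), "TM1", ch))
  # marginal: the talc threshold recovered from its own anchor classifies
  # as focused under the anchor-calibrated model
  m <- calibrate_density_model(
    c(1.05, 2.75), c(1, coefficient_from_threshold(um(26), ch)))
  expect_true(is_focused(um(26), "TM4", ch, density_g_ml = 2.75, dcm = m))
  expect_true(is_focused(um(1000), "TM1", ch))
  expect_error(is_focused(um(21), "TM4", ch), "density")
})

test_that("TM3 display conventions: formula vs rounded chain", {
  ch <- ref_channel()
  expect_equal(tm3_display_threshold(ch), 16.89722, tolerance = 1e-6)
  expect_equal(tm3_display_threshold(ch, round_chain = TRUE), 16.5)
})
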