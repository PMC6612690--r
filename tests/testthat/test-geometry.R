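test_that("feed per rotation is pitch times collimation", {
  expect_equal(feed_per_rotation(0.99, 80), 79.2)
  expect_equal(feed_per_rotation(0.83, 32), 26.56)
  expect_equal(feed_per_rotation(1.0, 0), 0)
  expect_error(feed_per_rotation(-1, 32), "pitch")
  expect_error(feed_per_rotation(0.8, -5), "pitch")
})

test_that("stripe tilt follows the unwrapped helix geometry", {
  expect_equal(stripe_tilt_angle(0, 250), 0)
  expect_equal(stripe_tilt_angle(79.2, 250),
               atan(79.2 / (2 * pi * 250)) * 180 / pi)
  expect_equal(round(stripe_tilt_angle(79.2, 250), 2), 2.89)
  expect_equal(round(stripe_tilt_angle(26.56, 250), 4), 0.9687)
  expect_error(stripe_tilt_angle(10, 0), "plate_radius")
  # monotone in feed, decreasing in radius
  feeds <- seq(5, 120, by = 5)
  expect_true(all(diff(vapply(feeds, stripe_tilt_angle, numeric(1),
                              plate_radius = 250)) > 0))
  radii <- seq(50, 400, by = 25)
  expect_true(all(diff(vapply(radii, function(r) stripe_tilt_angle(40, r),
                              numeric(1))) < 0))
})

test_that("beam width magnification and its round trip", {
  g <- scanner_geometry(fid = 600, plate_radius = 250)
  expect_equal(correct_beam_width(22.8, g), 22.8 * 600 / 350)
  g2 <- scanner_geometry(fid = 2, plate_radius = 1,
                         focus_collimator_distance = 0.5)
  expect_equal(correct_beam_width(1, g2), 2)
  # linear in the measured width
  expect_equal(correct_beam_width(7, g), 7 / 3.5 * correct_beam_width(3.5, g))
  # round trip with the plate-level projection
  for (w in c(32, 39, 80, 88))
    expect_equal(correct_beam_width(w * g$fsd / g$fid, g), w)
  expect_error(correct_beam_width(Inf, g))
  expect_error(correct_beam_width(-1, g))
})

test_that("dose efficiency matches nominal over actual and is reciprocal", {
  expect_equal(round(dose_efficiency(32, 39.0), 2), 0.82)
  expect_equal(round(dose_efficiency(80, 88.4), 2), 0.90)
  expect_equal(dose_efficiency(55, 55), 1)
  set.seed(7)
  for (k in 1:20) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100)
    expect_equal(dose_efficiency(a, b) * dose_efficiency(b, a), 1)
  }
  expect_error(dose_efficiency(32, 0), "actual_bw")
  expect_error(dose_efficiency(0, 39), "nominal_bw")
})

test_that("stripe separability compares footprint with feed", {
  g <- scanner_geometry(fid = 600, plate_radius = 250)
  b <- beam_model(39, penumbra_iso = 0)
  a <- acquisition_params(32, 0.83)
  expect_true(stripes_separable(b, g, a))  # 39 * 350/600 = 22.75 < 26.56
  g_small_fsd <- scanner_geometry(fid = 600, plate_radius = 0.1,
                                  focus_collimator_distance = 200)
  expect_false(stripes_separable(b, g_small_fsd, a))
  # the penumbra widens the footprint
  b_pen <- beam_model(39, penumbra_iso = 5)
  a_tight <- acquisition_params(32, 0.78)  # feed 24.96 between the two footprints
  expect_true(stripes_separable(b, g, a_tight))
  expect_false(stripes_separable(b_pen, g, a_tight))
})

test_that("constructors reject invalid physics", {
  expect_error(scanner_geometry(fid = 200, plate_radius = 250), "fid > plate_radius")
  expect_error(scanner_geometry(fid = 600, plate_radius = 250,
                                focus_collimator_distance = 400),
               "focus_collimator_distance")
  expect_error(acquisition_params(32, -1), "positive")
  expect_error(acquisition_params(32, 0.8, scan_range_d = 0), "positive")
  expect_error(acquisition_params(32, 0.8, active_collimator = "yes"), "TRUE/FALSE")
  expect_error(beam_model(10, penumbra_iso = 12), "umbra")
  expect_error(beam_model(-5, penumbra_iso = 1), "positive")
  # derived FSD is strictly positive and penumbra follows the focal spot
  g <- scanner_geometry(fid = 600, plate_radius = 250, focal_spot_z = 1,
                        focus_collimator_distance = 200)
  expect_gt(g$fsd, 0)
  expect_equal(beam_model(39, geometry = g)$penumbra_iso, 1 * (600 - 200) / 200)
})
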