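test_that("PV to exposure follows the log response", {
  expect_equal(pv_to_exposure(0, 1024), 1)
  expect_equal(pv_to_exposure(1024, 1024), 10)
  expect_equal(pv_to_exposure(512, 1024), sqrt(10))
  expect_error(pv_to_exposure(100, 0), "gray_level")
  expect_error(pv_to_exposure(-3, 1024), "PV")
})

test_that("z profile reduces the image along the circumference", {
  img <- stripe_image(matrix(7, 40, 30), 0.5, units = "exposure")
  p <- z_profile(img)
  expect_equal(p$values, rep(7, 40))
  expect_equal(p$spacing, 0.5)
  # single-column ROI returns that column verbatim
  m <- matrix(runif(40 * 30), 40, 30)
  img2 <- stripe_image(m, 0.5, units = "exposure")
  p2 <- z_profile(img2, roi = list(u = c(5.2, 5.3)))  # column 11 centre at 5.25
  expect_equal(p2$values, m[, 11])
  expect_error(z_profile(img2, roi = list(u = c(100, 200))), "empty ROI")
})

test_that("overranging and reduction ratio arithmetic", {
  expect_equal(overranging(276.6, 160), 58.3)
  expect_equal(overranging(360.6, 160), 100.3)
  expect_equal(overranging(160, 160), 0)
  expect_warning(or <- overranging(150, 160), "negative")
  expect_equal(or, -5)
  expect_error(overranging(NA, 160), "finite")
  expect_equal(round(reduction_ratio(58.3, 48.2), 1), 17.3)
  expect_equal(round(reduction_ratio(100.3, 83.1), 1), 17.1)
  expect_equal(reduction_ratio(40, 40), 0)
  expect_error(reduction_ratio(0, 10), "positive")
})

test_that("stripe detection finds each rotation inside the range", {
  sim <- small_sim(coll = 32, pitch = 1.0, d = 96)  # feed 32: 3 in-range stripes
  st <- detect_stripes(sim$image)
  in_range <- Filter(function(s) !s$in_taper, st)
  expect_true(abs(length(in_range) - 3) <= 1)
  for (s in in_range) expect_lt(abs(s$tilt - sim$truth$tilt_true), 0.1)
  blank <- stripe_image(matrix(1, 60, 60), 0.5, units = "exposure")
  expect_error(detect_stripes(blank), "no stripes")
  pv <- encode_pv(sim$image)
  expect_error(detect_stripes(pv), "exposure units")
})

test_that("perpendicular profile of an untilted stripe is a column cut", {
  # horizontal band: trapezoid in z, constant along u
  z <- (seq_len(200) - 0.5) * 0.5
  band <- ifelse(abs(z - 50) <= 5, 1000,
                 pmax(0, 1000 * (9 - abs(z - 50)) / 4))
  img <- stripe_image(matrix(band, 200, 80), 0.5, units = "exposure")
  st <- detect_stripes(img)
  expect_length(st, 1)
  expect_lt(abs(st[[1]]$tilt), 0.05)
  prof <- extract_perpendicular_profile(img, st[[1]], length = 30)
  # against the analytic band evaluated by the same bilinear rule
  ref <- approx(z, band, xout = st[[1]]$centroid[["z"]] + prof$positions)$y
  expect_equal(prof$values, ref, tolerance = 1e-9)
  expect_lt(abs(measure_fwhm(prof) - 14), 0.5)  # top 10, base 18 -> FWHM 14
  expect_error(extract_perpendicular_profile(img, st[[1]], length = 500),
               "exits the image")
  expect_error(extract_perpendicular_profile(img, st[[1]], length = 10),
               "exceed the stripe base")
})

test_that("overbeaming analysis recovers the configured beam width", {
  sim <- small_sim(coll = 32, pitch = 1.2, d = 60)
  g <- test_geometry()
  ob <- analyze_overbeaming(sim$image, g, 32)
  expect_lt(abs(ob$beam_width[["mean"]] / 39 - 1), 0.02)
  expect_gte(ob$dose_efficiency[["mean"]], 0)
  expect_equal(ob$dose_efficiency[["mean"]], mean(32 / ob$beam_width_per_stripe))
  ob1 <- analyze_overbeaming(sim$image, g, 32, n_stripes = 1)
  expect_equal(ob1$beam_width[["sd"]], 0)
  expect_error(analyze_overbeaming(sim$image, g, -3), "nominal_bw")
})

test_that("overlapping stripes abort the overbeaming analysis", {
  g <- scanner_geometry(fid = 600, plate_radius = 50)
  b <- beam_model(39, geometry = g)
  a <- acquisition_params(32, 0.5, scan_range_d = 60)
  expect_false(stripes_separable(b, g, a))
  sim <- overlap_sim()
  expect_error(analyze_overbeaming(sim$image, g, 32), "overlap")
})

test_that("separability predicts the presence of an inter-stripe gap", {
  # separable case: trough between adjacent ridges falls below 10% of peak
  sim <- small_sim(coll = 32, pitch = 1.2, d = 60)
  g <- test_geometry()
  b <- test_beam(39)
  a <- acquisition_params(32, 1.2, scan_range_d = 60)
  expect_true(stripes_separable(b, g, a))
  img <- sim$image
  st <- Filter(function(s) !s$in_taper, detect_stripes(img))
  zc <- sort(vapply(st, function(s) s$centroid[["z"]], numeric(1)))
  j <- ncol(img$data) %/% 2
  col <- img$data[, j]
  z <- img$z_min + (seq_along(col) - 0.5) * img$pixel_spacing
  ridge <- vapply(st, function(s)
    s$centroid[["z"]] + ((j - 0.5) * img$pixel_spacing - s$centroid[["u"]]) *
      tan(s$tilt * pi / 180), numeric(1))
  ridge <- sort(ridge)
  gap <- col[z > ridge[1] & z < ridge[2]]
  expect_lt(min(gap), 0.1 * max(col))
  # non-separable case: the trough stays high
  sim2 <- overlap_sim()
  col2 <- sim2$image$data[, ncol(sim2$image$data) %/% 2]
  z2 <- sim2$image$z_min + (seq_along(col2) - 0.5) * sim2$image$pixel_spacing
  inner <- col2[z2 > 20 & z2 < 40]  # well inside the merged band
  expect_gt(min(inner), 0.1 * max(col2))
})

test_that("overranging analysis matches the simulation truth", {
  sim <- small_sim(coll = 32, pitch = 1.2, d = 60)
  res <- analyze_overranging(sim$image)
  tol <- max(1, 2 * sim$image$pixel_spacing)
  expect_lt(abs(res$overranging - sim$truth$overranging_true), tol)
  expect_equal(res$overranging,
               (res$actual_exposure_length - 60) / 2)
  flat <- stripe_image(matrix(5, 60, 60), 0.5, units = "exposure",
                       metadata = list(acquisition = list(
                         nominal_collimation = 32, pitch = 1)))
  expect_error(analyze_overranging(flat), "peak not resolved")
})

test_that("flat-plate mode measures widths at unit magnification", {
  tra <- trapezoid_profile(top = 4, base = 8)
  res <- analyze_flat_profile(tra)
  expect_lt(abs(res$beam_width - 6), tra$spacing)
  expect_null(res$overranging)
  g <- test_geometry(); b <- test_beam(39)
  a <- acquisition_params(32, 1.2, scan_range_d = 60)
  ax <- simulate_flat_profile(g, b, a, mode = "axial", spacing = 0.2)
  expect_lt(abs(analyze_flat_profile(ax)$beam_width - 39), 0.2)
  he <- simulate_flat_profile(g, b, a, mode = "helical", spacing = 0.2)
  res2 <- analyze_flat_profile(he, scan_range_d = 60)
  expect_true(res2$actual_exposure_length > 60)
  expect_equal(res2$overranging, (res2$actual_exposure_length - 60) / 2)
})

test_that("results are invariant to stripe phase and plate decomposition", {
  sim <- small_sim(coll = 32, pitch = 1.2, d = 60)
  g <- test_geometry()
  img <- sim$image
  base_bw <- analyze_overbeaming(img, g, 32)$beam_width[["mean"]]
  base_or <- analyze_overranging(img)$overranging
  # split/stitch: identical pixels, identical results
  stitched <- stitch_plates(split_into_plates(img, 5))
  expect_identical(stitched$data, img$data)
  expect_equal(analyze_overbeaming(stitched, g, 32)$beam_width[["mean"]], base_bw)
  # circular rotation of the unwrapped circumference (stripe phase)
  k <- ncol(img$data) %/% 3
  rolled <- stripe_image(img$data[, c((k + 1):ncol(img$data), 1:k)],
                         img$pixel_spacing, units = "exposure",
                         z_min = img$z_min, metadata = img$metadata)
  expect_equal(analyze_overranging(rolled)$overranging, base_or, tolerance = 1e-9)
  bw_roll <- analyze_overbeaming(rolled, g, 32)$beam_width[["mean"]]
  expect_lt(abs(bw_roll / base_bw - 1), 0.005)
})
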