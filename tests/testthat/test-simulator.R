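test_that("aperture profile is a trapezoid with exact FWHM", {
  b <- beam_model(39, penumbra_iso = 2)
  expect_equal(aperture_profile(0, b), 1)
  expect_equal(aperture_profile(c(-39 / 2, 39 / 2), b), c(0.5, 0.5))
  expect_equal(aperture_profile(c(-30, 30), b), c(0, 0))  # outside the base
  expect_equal(aperture_profile(18.5, b), 1)              # umbra edge
  # rectangle limit: no penumbra
  b0 <- beam_model(32, penumbra_iso = 0)
  expect_equal(aperture_profile(c(-15.99, 15.99), b0), c(1, 1))
  expect_equal(aperture_profile(c(-16.01, 16.01), b0), c(0, 0))
})

test_that("collimator schedule clamps only near the range boundaries", {
  b <- beam_model(39, penumbra_iso = 2)
  hb <- (39 + 2) / 2
  a_off <- acquisition_params(32, 1.0, scan_range_d = 160)
  a_on <- acquisition_params(32, 1.0, scan_range_d = 160, active_collimator = TRUE)
  z <- seq(-40, 200, by = 2.5)
  off <- collimator_schedule(z, a_off, b)
  expect_equal(off$upper_edge - off$lower_edge, rep(2 * hb, length(z)))
  on <- collimator_schedule(z, a_on, b)
  # mid-scan: identical to the open beam
  mid <- z > hb & z < 160 - hb
  expect_equal(on$lower_edge[mid], off$lower_edge[mid])
  expect_equal(on$upper_edge[mid], off$upper_edge[mid])
  # beam centre at a range boundary: exposed width about half the open width
  at0 <- collimator_schedule(0, a_on, b)
  ratio <- (at0$upper_edge - at0$lower_edge) / (2 * hb)
  expect_lte(ratio, 0.55)
  expect_gte(ratio, 0.45)
  atd <- collimator_schedule(160, a_on, b)
  expect_equal(atd$upper_edge - atd$lower_edge, hb)
  # the aperture never widens beyond fully open
  expect_true(all(on$upper_edge - on$lower_edge <= 2 * hb + 1e-12))
})

test_that("simulated stripe width matches the thin-ray projection", {
  sim <- small_sim(coll = 32, pitch = 1.2, d = 60)
  g <- test_geometry()
  img <- sim$image
  st <- Filter(function(s) !s$in_taper, detect_stripes(img))
  expect_gte(length(st), 1)
  s <- st[[which.min(abs(vapply(st, function(r) r$centroid[["z"]], numeric(1)) - 30))]]
  prof <- extract_perpendicular_profile(img, s, length = 1.1 * 38.4)
  fwhm <- measure_fwhm(prof)
  expect_lt(abs(fwhm - 39 * g$fsd / g$fid), img$pixel_spacing)
})

test_that("simulated stripe tilt matches the helix geometry", {
  sim <- small_sim(coll = 32, pitch = 1.2, d = 60)
  st <- Filter(function(s) !s$in_taper, detect_stripes(sim$image))
  tilts <- vapply(st, function(s) s$tilt, numeric(1))
  expect_true(all(abs(tilts - sim$truth$tilt_true) < 0.05))
})

test_that("active collimator strictly shortens the exposure", {
  off <- small_sim(coll = 32, pitch = 1.2, d = 60, ac = FALSE)
  on <- small_sim(coll = 32, pitch = 1.2, d = 60, ac = TRUE)
  expect_lt(on$truth$exposure_length, off$truth$exposure_length)
  expect_lt(on$truth$overranging_true, off$truth$overranging_true)
})

test_that("simulation truth ties overranging to the exposure length", {
  sim <- small_sim(coll = 32, pitch = 1.2, d = 60)
  expect_equal(sim$truth$overranging_true,
               (sim$truth$exposure_length - 60) / 2)
})

test_that("PV encoding inverts the CR response up to quantisation", {
  # closed-form anchor points of the log response
  px <- 0.4
  e <- matrix(c(1, 10, 10^0.5, 500, 999, 0, 123.4, 2.5), 2, 4)
  img <- stripe_image(e, px, units = "exposure")
  pv <- encode_pv(img, gray_level_g = 1024)
  expect_equal(pv$data[1, 1], 0)       # E = 1 -> PV 0
  expect_equal(pv$data[2, 1], 1024)    # E = 10 -> PV 1024
  expect_equal(pv$data[1, 2], 512)     # E = sqrt(10) -> PV 512
  expect_equal(pv$data[2, 3], 0)       # non-positive exposure -> PV 0
  expect_equal(pv$metadata$n_nonpositive_exposure, 1)
  back <- pv_to_exposure(pv, 1024)
  pos <- e > 0
  expect_true(all(abs(back$data[pos] / e[pos] - 1) < 10^(0.5 / 1024) - 1 + 1e-12))
  expect_error(encode_pv(pv), "exposure units")
})

test_that("plate splitting and stitching are exact inverses", {
  sim <- small_sim(coll = 32, pitch = 1.2, d = 60)
  pv <- encode_pv(sim$image)
  one <- split_into_plates(pv, 1)
  expect_identical(one[[1]]$data, pv$data)
  five <- split_into_plates(pv, 5)
  widths <- vapply(five, function(p) ncol(p$data), integer(1))
  expect_equal(sum(widths), ncol(pv$data))
  back <- stitch_plates(five)
  expect_identical(back$data, pv$data)
  # with overlap, the averaged seams still reproduce identical data exactly
  ov <- stitch_plates(split_into_plates(pv, 5, overlap = 2))
  expect_identical(ov$data, pv$data)
  expect_error(split_into_plates(pv, 5, overlap = 1e5), "overlap")
})

test_that("noise is multiplicative, seeded and reproducible", {
  a <- small_sim(coll = 32, pitch = 1.2, d = 60, noise_sd = 0.02, seed = 11)
  b <- small_sim(coll = 32, pitch = 1.2, d = 60, noise_sd = 0.02, seed = 11)
  # the cache returns the same object; recompute b independently
  g <- test_geometry(); bm <- test_beam(39)
  acq <- acquisition_params(32, 1.2, scan_range_d = 60)
  grid <- auto_grid(g, bm, acq, pixel_spacing = 0.4)
  b2 <- simulate_stripe_image(g, bm, acq, grid, noise_sd = 0.02, seed = 11,
                              step_deg = 1)
  expect_identical(a$image$data, b2$image$data)
  b3 <- simulate_stripe_image(g, bm, acq, grid, noise_sd = 0.02, seed = 12,
                              step_deg = 1)
  expect_false(identical(a$image$data, b3$image$data))
})

test_that("a grid too coarse for the penumbra is flagged", {
  g <- test_geometry(); bm <- test_beam(39)  # plate-level penumbra ~1.17 mm
  acq <- acquisition_params(32, 1.2, scan_range_d = 40)
  grid <- auto_grid(g, bm, acq, pixel_spacing = 1.5, u_extent = 120)
  sim <- simulate_stripe_image(g, bm, acq, grid, step_deg = 2)
  expect_true(length(sim$image$metadata$warnings) > 0)
  expect_match(sim$image$metadata$warnings[1], "penumbra")
})

test_that("doubling the grid resolution barely moves the recovered widths", {
  coarse <- small_sim(coll = 32, pitch = 1.2, d = 60, px = 0.4)
  fine <- small_sim(coll = 32, pitch = 1.2, d = 60, px = 0.2)
  g <- test_geometry()
  bw <- vapply(list(coarse, fine), function(s)
    analyze_overbeaming(s$image, g, 32)$beam_width[["mean"]], numeric(1))
  or <- vapply(list(coarse, fine), function(s)
    analyze_overranging(s$image)$overranging, numeric(1))
  expect_lt(abs(diff(bw)), 0.2)  # half a coarse pixel
  expect_lt(abs(diff(or)), 0.2)
})
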