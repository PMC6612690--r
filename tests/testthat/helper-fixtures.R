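# shared fixtures: geometries, beams and memoised simulations so the forward
# model runs once per parameter set for the whole suite

test_geometry <- function(fid = 600, plate_radius = 250)
  scanner_geometry(fid = fid, plate_radius = plate_radius)

test_beam <- function(bw = 39, ...) beam_model(bw, geometry = test_geometry(), ...)

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) assign(key, force(expr), envir = .sim_cache)
  .sim_cache[[key]]
}

# small, fast stripe simulation used by unit tests (coarse grid, short range)
small_sim <- function(coll = 32, pitch = 1.0, ac = FALSE, bw = 39, d = 60,
                      px = 0.4, u_extent = NULL, noise_sd = 0, seed = NULL,
                      step_deg = 1) {
  key <- paste("s", coll, pitch, ac, bw, d, px, u_extent %||% "full", noise_sd,
               seed %||% "x", step_deg, sep = "_")
  cached(key, {
    g <- test_geometry()
    b <- test_beam(bw)
    a <- acquisition_params(coll, pitch, scan_range_d = d,
                            active_collimator = ac)
    grid <- auto_grid(g, b, a, pixel_spacing = px, u_extent = u_extent)
    simulate_stripe_image(g, b, a, grid, noise_sd = noise_sd, seed = seed,
                          step_deg = step_deg)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full simulate -> encode -> split -> stitch -> decode -> analyze round trip
# at the default grid (0.2 mm/px, full circumference), one row per case
acceptance_case <- function(coll, pitch, ac) {
  key <- sprintf("acc_%g_%g_%d", coll, pitch, ac)
  cached(key, {
    g <- test_geometry()
    bw_true <- if (coll == 32) 39 else 88
    b <- test_beam(bw_true)
    a <- acquisition_params(coll, pitch, active_collimator = ac)
    sim <- simulate_stripe_image(g, b, a)
    img <- pv_to_exposure(stitch_plates(split_into_plates(encode_pv(sim$image), 5)))
    ob <- analyze_overbeaming(img, g, coll)
    orr <- analyze_overranging(img)
    rm(img); gc(verbose = FALSE)
    data.frame(coll = coll, pitch = pitch, ac = ac, bw_true = bw_true,
               bw = ob$beam_width[["mean"]], bw_sd = ob$beam_width[["sd"]],
               or_true = sim$truth$overranging_true, or = orr$overranging,
               exposure_length = orr$actual_exposure_length,
               pixel = sim$image$pixel_spacing)
  })
}

acceptance_sweep <- function() {
  cases <- rbind(expand.grid(coll = c(32, 80), pitch = c(0.83, 0.87, 0.99, 1.48),
                             ac = FALSE),
                 data.frame(coll = c(32, 80), pitch = c(1.48, 0.99), ac = TRUE))
  do.call(rbind, lapply(seq_len(nrow(cases)), function(i)
    acceptance_case(cases$coll[i], cases$pitch[i], cases$ac[i])))
}

# a deliberately non-separable configuration: small plate radius at pitch 0.5
overlap_sim <- function() {
  cached("overlap_sim", {
    g <- scanner_geometry(fid = 600, plate_radius = 50)
    b <- beam_model(39, geometry = g)
    a <- acquisition_params(32, 0.5, scan_range_d = 60)
    grid <- auto_grid(g, b, a, pixel_spacing = 0.4)
    simulate_stripe_image(g, b, a, grid, step_deg = 1)
  })
}

# analytic profiles for the estimator oracles
triangle_profile <- function(base = 10, apex = 1, background = 0, spacing = 0.05) {
  z <- seq(-base, base, by = spacing)
  dose_profile(background + pmax(0, apex * (1 - abs(z) / (base / 2))), spacing,
               positions = z)
}

trapezoid_profile <- function(top = 4, base = 8, apex = 1, background = 0,
                              spacing = 0.05, halfspan = NULL) {
  ramp <- (base - top) / 2
  if (is.null(halfspan)) halfspan <- base
  z <- seq(-halfspan, halfspan, by = spacing)
  v <- ifelse(abs(z) <= top / 2, apex,
              pmax(0, apex * (base / 2 - abs(z)) / ramp))
  dose_profile(background + v, spacing, positions = z)
}

rectangle_profile <- function(width = 6, apex = 1, spacing = 0.05) {
  z <- seq(-width, width, by = spacing)
  dose_profile(ifelse(abs(z) < width / 2, apex, 0), spacing, positions = z)
}
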