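#' Simulation grid specification
#'
#' @param pixel_spacing Pixel spacing, mm/pixel (default 0.2).
#' @param z_extent Image height along the slice direction, mm.
#' @param u_extent Unwrapped circumference covered, mm; must not exceed the
#'   full circumference of the plate.
#' @param z_min z coordinate of the lower image edge, mm. `NULL` centres the
#'   grid on the scan range midpoint.
#' @return An object of class `grid_spec`.
#' @seealso [auto_grid()] for a grid sized from beam and acquisition.
#' @export
grid_spec <- function(pixel_spacing = 0.2, z_extent, u_extent, z_min = NULL) {
  if (!is.finite(pixel_spacing) || pixel_spacing <= 0)
    stop("grid_spec: pixel_spacing must be positive")
  if (!is.finite(z_extent) || z_extent <= 0 || !is.finite(u_extent) || u_extent <= 0)
    stop("grid_spec: extents must be positive")
  structure(list(pixel_spacing = pixel_spacing, z_extent = z_extent,
                 u_extent = u_extent, z_min = z_min),
            class = "grid_spec")
}

#' Grid sized to an acquisition
#'
#' Builds a [grid_spec()] whose z-extent covers the planned scan range, the
#' lead-in/out travel and the beam footprint on the plate with a 10 mm
#' margin, and whose u-extent defaults to the full plate circumference.
#'
#' @inheritParams simulate_stripe_image
#' @param pixel_spacing mm/pixel.
#' @param u_extent mm of unwrapped circumference; default the full cylinder.
#' @export
auto_grid <- function(geometry, beam, acquisition, pixel_spacing = 0.2,
                      u_extent = NULL) {
  stopifnot(inherits(geometry, "scanner_geometry"), inherits(beam, "beam_model"),
            inherits(acquisition, "acquisition_params"))
  if (is.null(u_extent)) u_extent <- 2 * pi * geometry$plate_radius
  feed <- feed_per_rotation(acquisition$pitch, acquisition$nominal_collimation)
  hb <- (beam$actual_bw_iso + beam$penumbra_iso) / 2
  lead <- acquisition$overtravel_rotations * feed + hb
  # widest beam footprint on the plate occurs for oblique passes; bound with
  # the focus-plate distance at 30 degrees off the radial pass
  rho30 <- sqrt(geometry$fid^2 + geometry$plate_radius^2 -
                  2 * geometry$fid * geometry$plate_radius * cos(pi / 6))
  half_plate <- hb * rho30 / geometry$fid
  margin <- 10
  z_extent <- acquisition$scan_range_d + 2 * (lead + half_plate + margin)
  grid_spec(pixel_spacing = pixel_spacing, z_extent = z_extent,
            u_extent = u_extent, z_min = -(lead + half_plate + margin))
}

#' Relative z-aperture intensity at isocenter
#'
#' Symmetric trapezoid centred at 0: unity over the umbra, linear penumbra
#' ramps on each side, zero outside the base. Its FWHM equals
#' `actual_bw_iso` exactly.
#'
#' @param z_off_iso z offset from the beam centre at isocenter, mm (vector).
#' @param beam A [beam_model()].
#' @return Relative intensity in `[0, 1]`.
#' @export
aperture_profile <- function(z_off_iso, beam) {
  stopifnot(inherits(beam, "beam_model"))
  hu <- (beam$actual_bw_iso - beam$penumbra_iso) / 2
  hbase <- (beam$actual_bw_iso + beam$penumbra_iso) / 2
  az <- abs(z_off_iso)
  out <- numeric(length(az))
  out[az <= hu] <- 1
  ramp <- az > hu & az < hbase
  if (beam$penumbra_iso > 0)
    out[ramp] <- (hbase - az[ramp]) / beam$penumbra_iso
  out
}

#' Dynamic z-collimator blade schedule
#'
#' Returns the lower and upper aperture edges in absolute isocenter z for a
#' beam centred at `z_table`. Without the active collimator the edges sit at
#' `z_table +/- base/2` throughout. With it, the blade facing outside the
#' planned range `[0, d]` is clamped against the range boundary during the
#' opening and closing phases, lagging the beam centre by a fraction
#' `min(1, ramp_rotations / 0.5)`; at the default ramp the shuttered width
#' when the beam centre crosses a range boundary is exactly half the fully
#' open width. Mid-scan both edges are fully open.
#'
#' @param z_table Beam centre position(s) at isocenter, mm.
#' @param acquisition An [acquisition_params()].
#' @param beam A [beam_model()] (sets the fully open base width).
#' @return A list with numeric vectors `lower_edge` and `upper_edge` (mm).
#' @export
collimator_schedule <- function(z_table, acquisition, beam) {
  stopifnot(inherits(acquisition, "acquisition_params"), inherits(beam, "beam_model"))
  hb <- (beam$actual_bw_iso + beam$penumbra_iso) / 2
  if (!acquisition$active_collimator)
    return(list(lower_edge = z_table - hb, upper_edge = z_table + hb))
  d <- acquisition$scan_range_d
  lag <- min(1, acquisition$ramp_rotations / 0.5)
  list(lower_edge = pmax(z_table - hb, lag * pmin(z_table, 0)),
       upper_edge = pmin(z_table + hb, d + lag * pmax(z_table - d, 0)))
}

#' Simulate a helical stripe image
#'
#' Forward model of the measurement: the source moves on a helix (one
#' rotation per `2*pi` of gantry angle, table feed `pitch x collimation` per
#' rotation) and entrance exposure accumulates on the unwrapped cylindrical
#' plate. Each plate point is exposed while it is the beam-entrance point of
#' the cylinder, weighted by inverse-square distance to the focus, incidence
#' obliquity and the in-plane fluence profile of the beam, with the
#' trapezoidal z-aperture evaluated along the ray and clipped by the dynamic
#' z-collimator schedule. The planned scan range is `[0, d]` at isocenter;
#' the beam centre travels from `-(overtravel x feed + base/2)` to
#' `d + overtravel x feed + base/2`.
#'
#' The returned exposure image is normalised to a peak of 1000. Ground truth
#' reports the configured beam width, the FWTM of the noiseless column-mean
#' z-profile (actual exposure length), the overranging it implies, and the
#' geometric stripe tilt.
#'
#' @param geometry A [scanner_geometry()].
#' @param beam A [beam_model()].
#' @param acquisition An [acquisition_params()].
#' @param grid A [grid_spec()]; default [auto_grid()].
#' @param noise_sd Relative standard deviation of multiplicative Gaussian
#'   noise on the exposure (0 = noiseless). The CR response is log-encoded,
#'   so multiplicative noise on E is additive on PV.
#' @param seed Integer seed for the noise generator.
#' @param step_deg Gantry-angle integration step, degrees.
#' @return A list with elements `image` (a [stripe_image()] in exposure
#'   units) and `truth` (class `simulation_truth`).
#' @export
simulate_stripe_image <- function(geometry, beam, acquisition, grid = NULL,
                                  noise_sd = 0, seed = NULL, step_deg = 0.5) {
  stopifnot(inherits(geometry, "scanner_geometry"), inherits(beam, "beam_model"),
            inherits(acquisition, "acquisition_params"))
  if (is.null(grid)) grid <- auto_grid(geometry, beam, acquisition)
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("simulate_stripe_image: noise_sd must be >= 0")
  circum <- 2 * pi * geometry$plate_radius
  if (grid$u_extent > circum + grid$pixel_spacing)
    stop("simulate_stripe_image: u_extent exceeds the plate circumference")

  feed <- feed_per_rotation(acquisition$pitch, acquisition$nominal_collimation)
  hb <- (beam$actual_bw_iso + beam$penumbra_iso) / 2
  d <- acquisition$scan_range_d
  z_start <- -(acquisition$overtravel_rotations * feed + hb)
  z_end <- d + acquisition$overtravel_rotations * feed + hb
  z_min <- if (is.null(grid$z_min)) d / 2 - grid$z_extent / 2 else grid$z_min
  nr <- max(8L, as.integer(round(grid$z_extent / grid$pixel_spacing)))
  nc <- max(8L, as.integer(round(grid$u_extent / grid$pixel_spacing)))

  warnings <- character()
  pen_plate <- beam$penumbra_iso * geometry$fsd / geometry$fid
  if (grid$pixel_spacing > pen_plate && beam$penumbra_iso > 0)
    warnings <- c(warnings,
                  sprintf("pixel spacing %.3g mm coarser than the plate-level penumbra %.3g mm",
                          grid$pixel_spacing, pen_plate))

  e <- cpp_accumulate_exposure(
    nr, nc, grid$pixel_spacing, z_min, 0,
    geometry$fid, geometry$plate_radius,
    beam$actual_bw_iso, beam$penumbra_iso, beam$fan_sigma_deg,
    feed, d, z_start, z_end, step_deg,
    acquisition$active_collimator, acquisition$ramp_rotations)
  peak <- max(e)
  if (peak <= 0) stop("simulate_stripe_image: no exposure recorded on the grid")
  e <- e * (1000 / peak)

  # ground truth from the noiseless column-mean z-profile
  zp <- dose_profile(rowMeans(e), grid$pixel_spacing, axis = "z",
                     positions = z_min + (seq_len(nr) - 0.5) * grid$pixel_spacing)
  fwtm <- measure_fwtm(zp)
  truth <- structure(list(
    actual_bw_iso = beam$actual_bw_iso,
    exposure_length = fwtm,
    overranging_true = (fwtm - d) / 2,
    tilt_true = stripe_tilt_angle(feed, geometry$plate_radius)),
    class = "simulation_truth")

  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    e <- e * pmax(0, 1 + stats::rnorm(length(e), sd = noise_sd))
    dim(e) <- c(nr, nc)
  }

  meta <- list(geometry = unclass(geometry), acquisition = unclass(acquisition),
               beam = unclass(beam),
               grid = list(pixel_spacing = grid$pixel_spacing,
                           z_extent = grid$z_extent, u_extent = grid$u_extent,
                           z_min = z_min),
               seed = seed, noise_sd = noise_sd, step_deg = step_deg,
               truth = unclass(truth), warnings = warnings,
               axis_convention = "rows = z increasing with table feed; columns = unwrapped circumference u")
  list(image = stripe_image(e, grid$pixel_spacing, units = "exposure",
                            z_min = z_min, u_min = 0, metadata = meta),
       truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(
    "<simulation_truth> BW %.1f mm | exposure length %.1f mm | overranging %.1f mm | tilt %.3f deg\n",
    x$actual_bw_iso, x$exposure_length, x$overranging_true, x$tilt_true))
  invisible(x)
}

#' Simulate a conventional flat-plate dose profile
#'
#' One-dimensional forward model of the conventional check: a plate at the
#' rotation centre records the z dose profile directly (unit magnification).
#' `mode = "axial"` exposes a stationary table (the profile is the z-aperture
#' itself; its FWHM is the actual beam width); `mode = "helical"` integrates
#' the moving beam over the same table travel as the stripe acquisition, so
#' its FWTM gives the actual exposure length.
#'
#' @inheritParams simulate_stripe_image
#' @param mode `"axial"` or `"helical"`.
#' @param spacing Sample spacing, mm.
#' @return A [dose_profile()] in exposure units, normalised to a peak of 1000.
#' @export
simulate_flat_profile <- function(geometry, beam, acquisition,
                                  mode = c("helical", "axial"), spacing = 0.2,
                                  noise_sd = 0, seed = NULL, step_deg = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(beam, "beam_model"), inherits(acquisition, "acquisition_params"))
  hb <- (beam$actual_bw_iso + beam$penumbra_iso) / 2
  d <- acquisition$scan_range_d
  if (mode == "axial") {
    z <- seq(-(hb + 15), hb + 15, by = spacing)
    v <- aperture_profile(z, beam) * 1000
  } else {
    feed <- feed_per_rotation(acquisition$pitch, acquisition$nominal_collimation)
    z_start <- -(acquisition$overtravel_rotations * feed + hb)
    z_end <- d + acquisition$overtravel_rotations * feed + hb
    z <- seq(z_start - hb - 15, z_end + hb + 15, by = spacing)
    nsteps <- max(1L, ceiling((z_end - z_start) / feed * 360 / step_deg))
    dtau <- (z_end - z_start) / feed / nsteps
    v <- numeric(length(z))
    for (k in seq_len(nsteps)) {
      zs <- z_start + feed * (k - 0.5) * dtau
      edges <- collimator_schedule(zs, acquisition, beam)
      a <- aperture_profile(z - zs, beam)
      a[z < edges$lower_edge | z > edges$upper_edge] <- 0
      v <- v + a * dtau
    }
    v <- v * (1000 / max(v))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v * pmax(0, 1 + stats::rnorm(length(v), sd = noise_sd))
  }
  dose_profile(v, spacing, axis = "z", units = "exposure", positions = z)
}

#' Encode exposure as computed-radiography pixel values
#'
#' Inverse of the CR response: `PV = G * log10(E)`, quantised to integers and
#' clipped to the bit depth. Non-positive exposures (unexposed background)
#' map to PV 0; their count is recorded in the image metadata.
#'
#' @param image_e A [stripe_image()] in exposure units.
#' @param gray_level_g Gray level G of the CR system (1024 here).
#' @param bit_depth Container bit depth (default 16).
#' @return A [stripe_image()] in PV units.
#' @seealso [pv_to_exposure()] for the forward conversion used in analysis.
#' @export
encode_pv <- function(image_e, gray_level_g = 1024, bit_depth = 16) {
  stopifnot(inherits(image_e, "stripe_image"))
  if (image_e$units != "exposure")
    stop("encode_pv: image is not in exposure units")
  if (!is.finite(gray_level_g) || gray_level_g <= 0)
    stop("encode_pv: gray_level_g must be positive")
  e <- image_e$data
  nonpos <- sum(e <= 0)
  pv <- matrix(0, nrow(e), ncol(e))
  ok <- e > 0
  pv[ok] <- gray_level_g * log10(e[ok])
  pv <- pmin(pmax(round(pv), 0), 2^bit_depth - 1)
  dim(pv) <- dim(e)
  meta <- image_e$metadata
  meta$gray_level <- gray_level_g
  meta$bit_depth <- bit_depth
  meta$n_nonpositive_exposure <- nonpos
  stripe_image(pv, image_e$pixel_spacing, units = "PV",
               z_min = image_e$z_min, u_min = image_e$u_min, metadata = meta)
}

#' Split a stripe image into imaging plates
#'
#' Partitions the unwrapped image along the circumferential axis into
#' `n_plates` sub-images (the physical setup wraps five plates around the
#' phantom). Each plate carries its layout index and u-offset; with
#' `overlap = 0`, [stitch_plates()] reproduces the original exactly.
#'
#' @param image A [stripe_image()].
#' @param n_plates Number of plates (>= 1, default 5).
#' @param overlap Overlap between adjacent plates, mm (each plate after the
#'   first is extended leftwards into its neighbour by this amount).
#' @return An object of class `plate_set`: a list of `stripe_image`s.
#' @export
split_into_plates <- function(image, n_plates = 5, overlap = 0) {
  stopifnot(inherits(image, "stripe_image"))
  n_plates <- as.integer(n_plates)
  if (n_plates < 1) stop("split_into_plates: n_plates must be >= 1")
  nc <- ncol(image$data)
  if (nc < n_plates) stop("split_into_plates: image too narrow for that many plates")
  o_px <- as.integer(round(overlap / image$pixel_spacing))
  bounds <- round(seq(0, nc, length.out = n_plates + 1))
  base_w <- min(diff(bounds))
  if (o_px < 0 || o_px >= base_w)
    stop("split_into_plates: overlap must be >= 0 and smaller than a plate width")
  plates <- vector("list", n_plates)
  for (k in seq_len(n_plates)) {
    first <- bounds[k] + 1L
    if (k > 1L) first <- first - o_px
    last <- bounds[k + 1L]
    meta <- image$metadata
    meta$plate <- list(layout_index = k, n_plates = n_plates,
                       overlap_px = if (k > 1L) o_px else 0L,
                       u_offset_px = first - 1L)
    plates[[k]] <- stripe_image(image$data[, first:last, drop = FALSE],
                                image$pixel_spacing, units = image$units,
                                z_min = image$z_min,
                                u_min = image$u_min + (first - 1L) * image$pixel_spacing,
                                metadata = meta)
  }
  structure(plates, class = "plate_set")
}

#' @export
print.plate_set <- function(x, ...) {
  cat(sprintf("<plate_set> %d plates, %s px each @ %.3g mm/px\n", length(x),
              paste(unique(vapply(x, function(p) paste(dim(p$data), collapse = "x"),
                                  character(1))), collapse = ", "),
              x[[1]]$pixel_spacing))
  invisible(x)
}
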