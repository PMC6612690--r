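#' Scanner geometry
#'
#' Geometric description of the CT gantry and the cylindrical imaging plate
#' wrapped around the measurement phantom. All lengths are in millimetres.
#' The focus--surface distance (FSD) is derived as `fid - plate_radius`: the
#' recorded stripe is entrance exposure on the cylinder, since the beam
#' exiting 500 mm of acrylic is attenuated to negligible levels.
#'
#' @param fid Focus--isocenter distance (FID), mm.
#' @param plate_radius Radius of the cylindrical plate, mm (250 mm for a
#'   500-mm phantom).
#' @param focal_spot_z z-extent of the focal spot, mm; drives the penumbra.
#' @param focus_collimator_distance Distance from focus to the z-collimator
#'   blades, mm; must be less than `fid - plate_radius`.
#' @return An object of class `scanner_geometry` with derived element `fsd`.
#' @examples
#' g <- scanner_geometry(fid = 600, plate_radius = 250)
#' g$fsd  # 350
#' @export
scanner_geometry <- function(fid = 600, plate_radius = 250, focal_spot_z = 1,
                             focus_collimator_distance = 200) {
  stopifnot(is.numeric(fid), is.numeric(plate_radius),
            is.numeric(focal_spot_z), is.numeric(focus_collimator_distance))
  if (!is.finite(fid) || !is.finite(plate_radius) || fid <= plate_radius ||
      plate_radius <= 0)
    stop("scanner_geometry: need fid > plate_radius > 0")
  if (focal_spot_z < 0)
    stop("scanner_geometry: focal_spot_z must be >= 0")
  if (focus_collimator_distance <= 0 ||
      focus_collimator_distance >= fid - plate_radius)
    stop("scanner_geometry: need 0 < focus_collimator_distance < fid - plate_radius")
  structure(list(fid = fid, plate_radius = plate_radius,
                 focal_spot_z = focal_spot_z,
                 focus_collimator_distance = focus_collimator_distance,
                 fsd = fid - plate_radius),
            class = "scanner_geometry")
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat(sprintf(
    "<scanner_geometry> FID %.1f mm | plate radius %.1f mm | FSD %.1f mm | focal spot z %.2f mm\n",
    x$fid, x$plate_radius, x$fsd, x$focal_spot_z))
  invisible(x)
}

#' Helical acquisition parameters
#'
#' @param nominal_collimation Nominal beam collimation (set beam width) at
#'   isocenter, mm (32 or 80 for the scanner studied here).
#' @param pitch Table feed per rotation divided by nominal collimation
#'   (dimensionless).
#' @param rotation_time Gantry rotation time, s.
#' @param scan_range_d Planned scan range `d`, mm (the range is `[0, d]` at
#'   isocenter).
#' @param active_collimator Logical; is the dynamic z-collimator engaged?
#' @param ramp_rotations Duration of the collimator open/close ramp, in
#'   rotations. The default 0.5 makes the shuttered width at the range
#'   boundaries approximately half the fully open width.
#' @param overtravel_rotations Extra table travel beyond the half-base
#'   clearance at each end, in rotations; models the part-rotations of data
#'   helical reconstruction needs beyond the planned range and makes the
#'   exposed length grow with pitch.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(nominal_collimation, pitch, rotation_time = 0.5,
                               scan_range_d = 160, active_collimator = FALSE,
                               ramp_rotations = 0.5, overtravel_rotations = 0.5) {
  vals <- c(nominal_collimation, pitch, rotation_time, scan_range_d)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("acquisition_params: collimation, pitch, rotation_time and scan_range_d must be positive")
  if (!is.logical(active_collimator) || length(active_collimator) != 1L)
    stop("acquisition_params: active_collimator must be TRUE/FALSE")
  if (!is.finite(ramp_rotations) || ramp_rotations < 0)
    stop("acquisition_params: ramp_rotations must be >= 0")
  if (!is.finite(overtravel_rotations) || overtravel_rotations < 0)
    stop("acquisition_params: overtravel_rotations must be >= 0")
  structure(list(nominal_collimation = nominal_collimation, pitch = pitch,
                 rotation_time = rotation_time, scan_range_d = scan_range_d,
                 active_collimator = active_collimator,
                 ramp_rotations = ramp_rotations,
                 overtravel_rotations = overtravel_rotations),
            class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf(
    "<acquisition_params> collimation %.0f mm | pitch %.2f | d %.0f mm | rotation %.2f s | active collimator %s\n",
    x$nominal_collimation, x$pitch, x$scan_range_d, x$rotation_time,
    if (x$active_collimator) "on" else "off"))
  invisible(x)
}

#' Trapezoidal beam model
#'
#' The z-aperture at isocenter is modelled as a symmetric trapezoid: a flat
#' umbra of width `actual_bw_iso - penumbra_iso` with one-sided linear
#' penumbra ramps of width `penumbra_iso`. Its FWHM equals `actual_bw_iso`
#' exactly; its base is `actual_bw_iso + penumbra_iso`.
#'
#' @param actual_bw_iso FWHM of the z-aperture at isocenter, mm (the actual
#'   beam width; exceeds the nominal collimation because of overbeaming).
#' @param penumbra_iso One-sided penumbra ramp width at isocenter, mm.
#'   Defaults to the focal-spot projection through the collimator,
#'   `focal_spot_z * (fid - fcd) / fcd`, when a geometry is supplied.
#' @param geometry Optional [scanner_geometry()], used only for the penumbra
#'   default.
#' @param fan_sigma_deg In-plane fluence concentration: entrance exposure is
#'   weighted by a Gaussian in fan angle with this standard deviation
#'   (degrees). It stands in for the strong beam-shaping filtration of
#'   clinical scanners, which confines the exposure of each plate point to
#'   source positions near its radial pass; `Inf` disables it.
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(actual_bw_iso, penumbra_iso = NULL, geometry = NULL,
                       fan_sigma_deg = 3) {
  if (is.null(penumbra_iso)) {
    if (is.null(geometry))
      stop("beam_model: give penumbra_iso or a geometry to derive it from")
    fcd <- geometry$focus_collimator_distance
    penumbra_iso <- geometry$focal_spot_z * (geometry$fid - fcd) / fcd
  }
  if (!is.finite(actual_bw_iso) || actual_bw_iso <= 0)
    stop("beam_model: actual_bw_iso must be positive")
  if (!is.finite(penumbra_iso) || penumbra_iso < 0)
    stop("beam_model: penumbra_iso must be >= 0")
  if (actual_bw_iso - penumbra_iso < 0)
    stop("beam_model: umbra (actual_bw_iso - penumbra_iso) would be negative")
  if (is.na(fan_sigma_deg) || fan_sigma_deg <= 0)
    stop("beam_model: fan_sigma_deg must be positive (use Inf to disable)")
  structure(list(actual_bw_iso = actual_bw_iso, penumbra_iso = penumbra_iso,
                 fan_sigma_deg = fan_sigma_deg),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("<beam_model> FWHM %.1f mm at isocenter | penumbra %.2f mm | base %.1f mm\n",
              x$actual_bw_iso, x$penumbra_iso, x$actual_bw_iso + x$penumbra_iso))
  invisible(x)
}

#' Table feed per gantry rotation
#'
#' Standard pitch definition: feed = pitch x nominal collimation.
#'
#' @param pitch Dimensionless pitch (> 0).
#' @param nominal_collimation Nominal collimation, mm (>= 0).
#' @return Feed in mm per rotation.
#' @examples
#' feed_per_rotation(0.99, 80)  # 79.2
#' @export
feed_per_rotation <- function(pitch, nominal_collimation) {
  if (!is.finite(pitch) || !is.finite(nominal_collimation) ||
      pitch <= 0 || nominal_collimation < 0)
    stop("feed_per_rotation: pitch must be > 0 and collimation >= 0")
  pitch * nominal_collimation
}

#' Tilt of a stripe on the unwrapped cylinder
#'
#' One gantry rotation advances the table by the feed while the source sweeps
#' the full circumference `2 * pi * plate_radius`, so the stripe of a helical
#' acquisition is tilted by `atan(feed / (2 * pi * plate_radius))` on the
#' unwrapped plate.
#'
#' @param feed Table feed per rotation, mm (>= 0).
#' @param plate_radius Cylinder radius, mm (> 0).
#' @return Tilt angle in degrees.
#' @export
stripe_tilt_angle <- function(feed, plate_radius) {
  if (!is.finite(plate_radius) || plate_radius <= 0)
    stop("stripe_tilt_angle: plate_radius must be > 0")
  if (!is.finite(feed) || feed < 0)
    stop("stripe_tilt_angle: feed must be >= 0")
  atan2(feed, 2 * pi * plate_radius) * 180 / pi
}

#' Magnify a plate-level FWHM to the rotation centre
#'
#' The beam diverges from the focus, so a width measured on the plate
#' (entrance surface, at FSD from the focus) corresponds to a width
#' `FWHM x FID / FSD` at the isocenter. This is the actual beam width used
#' for the dose-efficiency calculation.
#'
#' @param fwhm_plate FWHM measured on the stripe image, mm.
#' @param geometry A [scanner_geometry()].
#' @return Beam width at the rotation centre, mm.
#' @export
correct_beam_width <- function(fwhm_plate, geometry) {
  stopifnot(inherits(geometry, "scanner_geometry"))
  if (!is.finite(fwhm_plate) || fwhm_plate <= 0)
    stop("correct_beam_width: fwhm_plate must be positive and finite")
  fwhm_plate * geometry$fid / geometry$fsd
}

#' Dose efficiency
#'
#' Fraction of the emitted beam used for imaging: nominal beam width divided
#' by the measured actual beam width. Values below 1 quantify overbeaming.
#'
#' @param nominal_bw Nominal collimation, mm.
#' @param actual_bw Measured actual beam width, mm.
#' @return Dimensionless dose efficiency.
#' @examples
#' dose_efficiency(32, 39.0)  # 0.8205...
#' @export
dose_efficiency <- function(nominal_bw, actual_bw) {
  if (!is.finite(nominal_bw) || nominal_bw <= 0)
    stop("dose_efficiency: nominal_bw must be positive")
  if (!is.finite(actual_bw) || actual_bw <= 0)
    stop("dose_efficiency: actual_bw must be positive")
  nominal_bw / actual_bw
}

#' Are adjacent stripes separable on the plate?
#'
#' Adjacent rotations of the helix land `feed` apart along z on the plate.
#' Each stripe's footprint is the beam width projected to the entrance
#' surface plus twice the plate-level penumbra. Stripes are separable when
#' the footprint is strictly smaller than the feed; the large plate radius
#' (small FSD/FID) is what keeps stripes separate even at pitch < 1.
#'
#' @param beam A [beam_model()].
#' @param geometry A [scanner_geometry()].
#' @param acquisition An [acquisition_params()].
#' @return TRUE when the stripes do not overlap.
#' @export
stripes_separable <- function(beam, geometry, acquisition) {
  stopifnot(inherits(beam, "beam_model"), inherits(geometry, "scanner_geometry"),
            inherits(acquisition, "acquisition_params"))
  feed <- feed_per_rotation(acquisition$pitch, acquisition$nominal_collimation)
  if (feed <= 0) return(FALSE)
  scale <- geometry$fsd / geometry$fid
  footprint <- (beam$actual_bw_iso + 2 * beam$penumbra_iso) * scale
  footprint < feed
}
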