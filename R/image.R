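#' Stripe image container
#'
#' A 2-D scalar image of the unwrapped cylindrical plate. Rows index z
#' (increasing with table travel), columns index the unwrapped circumference
#' u; pixel centres sit at `(i - 0.5) * pixel_spacing` from the respective
#' origin. Units are either `"exposure"` (effective exposure E) or `"PV"`
#' (logarithmically encoded pixel values).
#'
#' @param data Numeric matrix (rows = z, columns = u).
#' @param pixel_spacing Pixel spacing, mm/pixel (isotropic).
#' @param units `"exposure"` or `"PV"`.
#' @param z_min z coordinate of the lower edge of the first row, mm.
#' @param u_min u coordinate of the left edge of the first column, mm.
#' @param metadata Named list of acquisition/simulation metadata carried with
#'   the image (written to the JSON sidecar on disk).
#' @return An object of class `stripe_image`.
#' @export
stripe_image <- function(data, pixel_spacing, units = c("exposure", "PV"),
                         z_min = 0, u_min = 0, metadata = list()) {
  units <- match.arg(units)
  if (!is.matrix(data) || !is.numeric(data))
    stop("stripe_image: data must be a numeric matrix")
  if (!is.finite(pixel_spacing) || pixel_spacing <= 0)
    stop("stripe_image: pixel_spacing must be positive")
  structure(list(data = data, pixel_spacing = pixel_spacing, units = units,
                 z_min = z_min, u_min = u_min, metadata = metadata),
            class = "stripe_image")
}

#' @export
print.stripe_image <- function(x, ...) {
  cat(sprintf(
    "<stripe_image> %d x %d px @ %.3g mm/px | z [%.1f, %.1f] mm | u [%.1f, %.1f] mm | units %s\n",
    nrow(x$data), ncol(x$data), x$pixel_spacing,
    x$z_min, x$z_min + nrow(x$data) * x$pixel_spacing,
    x$u_min, x$u_min + ncol(x$data) * x$pixel_spacing, x$units))
  invisible(x)
}

#' @export
dim.stripe_image <- function(x) dim(x$data)

# row-centre z coordinates / column-centre u coordinates
z_coords <- function(image) image$z_min + (seq_len(nrow(image$data)) - 0.5) * image$pixel_spacing
u_coords <- function(image) image$u_min + (seq_len(ncol(image$data)) - 0.5) * image$pixel_spacing

#' One-dimensional dose profile
#'
#' Uniformly sampled intensity versus position, the input to the FWHM/FWTM
#' estimators. Positions are sample centres at `(i - 0.5) * spacing` unless
#' explicit positions are given.
#'
#' @param values Numeric vector of intensities (at least 8 samples).
#' @param spacing Sample spacing, mm.
#' @param axis Orientation: `"z"` (slice direction) or
#'   `"perpendicular_to_stripe"`.
#' @param units `"exposure"` or `"PV"`.
#' @param positions Optional explicit sample positions, mm (must be uniform).
#' @return An object of class `dose_profile`.
#' @export
dose_profile <- function(values, spacing, axis = c("z", "perpendicular_to_stripe"),
                         units = "exposure", positions = NULL) {
  axis <- match.arg(axis)
  values <- as.numeric(values)
  if (length(values) < 8) stop("dose_profile: need at least 8 samples")
  if (!all(is.finite(values))) stop("dose_profile: values must be finite")
  if (!is.finite(spacing) || spacing <= 0) stop("dose_profile: spacing must be positive")
  if (is.null(positions)) positions <- (seq_along(values) - 0.5) * spacing
  if (length(positions) != length(values))
    stop("dose_profile: positions and values differ in length")
  structure(list(values = values, spacing = spacing, axis = axis,
                 units = units, positions = positions),
            class = "dose_profile")
}

#' @export
print.dose_profile <- function(x, ...) {
  cat(sprintf("<dose_profile> %d samples @ %.3g mm | axis %s | units %s | peak %.3g\n",
              length(x$values), x$spacing, x$axis, x$units, max(x$values)))
  invisible(x)
}

#' @export
length.dose_profile <- function(x) length(x$values)

# Bilinear interpolation of a stripe image at physical coordinates (vectorised).
# Points outside the image raise an error via the caller's check.
interp_bilinear <- function(image, z, u) {
  px <- image$pixel_spacing
  # fractional row/col index of the sample (1-based pixel centres)
  ri <- (z - image$z_min) / px + 0.5
  ci <- (u - image$u_min) / px + 0.5
  r0 <- pmin(pmax(floor(ri), 1), nrow(image$data) - 1)
  c0 <- pmin(pmax(floor(ci), 1), ncol(image$data) - 1)
  fr <- ri - r0
  fc <- ci - c0
  d <- image$data
  n <- nrow(d)
  idx <- function(r, c) (c - 1L) * n + r
  v00 <- d[idx(r0, c0)]; v10 <- d[idx(r0 + 1L, c0)]
  v01 <- d[idx(r0, c0 + 1L)]; v11 <- d[idx(r0 + 1L, c0 + 1L)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}
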