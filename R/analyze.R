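#' Convert CR pixel values to effective exposure
#'
#' The computed-radiography response is logarithmic: `E = 10^(PV / G)` with
#' gray level `G` (1024 for the system studied here). All width measurements
#' in this package are made on exposure-converted data; measuring on the
#' log-scaled pixel values would bias the widths.
#'
#' @param x A [stripe_image()], [dose_profile()] or numeric array in PV units.
#' @param gray_level_g Gray level G (> 0).
#' @return Same shape as `x`, in exposure units.
#' @export
pv_to_exposure <- function(x, gray_level_g = 1024) {
  if (!is.finite(gray_level_g) || gray_level_g <= 0)
    stop("pv_to_exposure: gray_level_g must be positive")
  if (inherits(x, "stripe_image")) {
    if (x$units != "PV") stop("pv_to_exposure: image is not in PV units")
    out <- x
    out$data <- 10^(x$data / gray_level_g)
    out$units <- "exposure"
    return(out)
  }
  if (inherits(x, "dose_profile")) {
    out <- x
    out$values <- 10^(x$values / gray_level_g)
    out$units <- "exposure"
    return(out)
  }
  if (any(x < 0)) stop("pv_to_exposure: PV must be >= 0")
  10^(x / gray_level_g)
}

#' Stitch imaging plates into one stripe image
#'
#' Concatenates the plates of a [split_into_plates()] decomposition (or
#' plates read from disk) along the circumferential axis in layout order,
#' averaging declared overlap regions. Seam positions are recorded in the
#' metadata so stripe detection can flag stripes centred on a seam.
#'
#' @param plates A `plate_set` or list of [stripe_image()]s.
#' @return A single [stripe_image()].
#' @export
stitch_plates <- function(plates) {
  if (inherits(plates, "stripe_image")) return(plates)
  if (!length(plates)) stop("stitch_plates: empty plate list")
  stopifnot(all(vapply(plates, inherits, logical(1), "stripe_image")))
  if (length(plates) == 1L) return(plates[[1L]])

  idx <- vapply(plates, function(p) {
    li <- p$metadata$plate$layout_index
    if (is.null(li)) NA_integer_ else as.integer(li)
  }, integer(1))
  if (!anyNA(idx)) {
    if (!setequal(idx, seq_along(plates)))
      stop("stitch_plates: layout indices are not contiguous: ",
           paste(sort(idx), collapse = ", "))
    plates <- plates[order(idx)]
  }

  sp <- vapply(plates, function(p) p$pixel_spacing, numeric(1))
  nr <- vapply(plates, function(p) nrow(p$data), integer(1))
  un <- vapply(plates, function(p) p$units, character(1))
  bad <- which(abs(sp - sp[1]) > 1e-9 | nr != nr[1] | un != un[1])
  if (length(bad))
    stop("stitch_plates: plates disagree in spacing, height or units: plate(s) ",
         paste(bad, collapse = ", "))

  out <- plates[[1L]]$data
  seams <- integer(0)
  for (k in 2L:length(plates)) {
    o <- plates[[k]]$metadata$plate$overlap_px
    if (is.null(o)) o <- 0L
    d <- plates[[k]]$data
    if (o > 0L) {
      nc0 <- ncol(out)
      out[, seq.int(nc0 - o + 1L, nc0)] <-
        (out[, seq.int(nc0 - o + 1L, nc0), drop = FALSE] +
           d[, seq_len(o), drop = FALSE]) / 2
      d <- d[, -seq_len(o), drop = FALSE]
    }
    seams <- c(seams, ncol(out))
    out <- cbind(out, d)
  }
  meta <- plates[[1L]]$metadata
  meta$plate <- NULL
  meta$seam_columns <- seams
  stripe_image(out, plates[[1L]]$pixel_spacing, units = plates[[1L]]$units,
               z_min = plates[[1L]]$z_min, u_min = plates[[1L]]$u_min,
               metadata = meta)
}

#' Detect stripes in a stripe image
#'
#' Thresholds the exposure image at 50% of its robust maximum (99.5th
#' percentile), labels connected components, discards components touching
#' the z borders of the image, and fits each stripe's tilt by
#' intensity-weighted total least squares (principal axis) of its
#' above-threshold pixels. Stripes whose centroid lies outside the planned
#' scan range (the collimator taper zones at scan start/end) are flagged
#' `in_taper` when acquisition metadata is available; stripes centred on a
#' stitching seam are flagged `on_seam`.
#'
#' @param image A [stripe_image()] in exposure units.
#' @param min_separation Minimum centroid z separation, mm; of two closer
#'   detections, the weaker is dropped.
#' @param min_pixels Minimum component size in pixels.
#' @return A list of `stripe_region` objects sorted by centroid z.
#' @export
detect_stripes <- function(image, min_separation = 1, min_pixels = 20) {
  stopifnot(inherits(image, "stripe_image"))
  if (image$units != "exposure")
    stop("detect_stripes: convert the image to exposure units first (pv_to_exposure)")
  d <- image$data
  rmax <- stats::quantile(d, 0.995, names = FALSE)
  thr <- 0.5 * rmax
  mask <- d > thr
  if (!any(mask)) stop("no stripes found: nothing above the detection threshold")
  labels <- EBImage::bwlabel(mask)
  idx <- which(mask)
  comp <- split(idx, labels[idx])
  px <- image$pixel_spacing
  zc <- z_coords(image)
  uc <- u_coords(image)
  nrow_d <- nrow(d)
  acq <- image$metadata$acquisition
  seams <- image$metadata$seam_columns

  regions <- list()
  for (ii in comp) {
    if (length(ii) < min_pixels) next
    ri <- ((ii - 1L) %% nrow_d) + 1L
    ci <- ((ii - 1L) %/% nrow_d) + 1L
    if (any(ri == 1L) || any(ri == nrow_d)) next   # cut off by the z border
    w <- d[ii]
    u <- uc[ci]; z <- zc[ri]
    W <- sum(w)
    mu_u <- sum(w * u) / W
    mu_z <- sum(w * z) / W
    # intensity-weighted principal axis -> tilt
    cuu <- sum(w * (u - mu_u)^2) / W
    czz <- sum(w * (z - mu_z)^2) / W
    cuz <- sum(w * (u - mu_u) * (z - mu_z)) / W
    ev <- eigen(matrix(c(cuu, cuz, cuz, czz), 2), symmetric = TRUE)$vectors[, 1]
    if (ev[1] < 0) ev <- -ev
    tilt <- atan2(ev[2], ev[1]) * 180 / pi
    bbox <- c(u_lo = min(u) - px / 2, u_hi = max(u) + px / 2,
              z_lo = min(z) - px / 2, z_hi = max(z) + px / 2)
    in_taper <- if (!is.null(acq))
      (mu_z < 0 || mu_z > acq$scan_range_d) else FALSE
    on_seam <- if (!is.null(seams) && length(seams))
      any(abs(mu_u - (image$u_min + seams * px)) < 2 * px) else FALSE
    regions[[length(regions) + 1L]] <- structure(
      list(centroid = c(u = mu_u, z = mu_z), tilt = tilt, extent = bbox,
           peak_value = max(d[ii]), n_pixels = length(ii),
           in_taper = in_taper, on_seam = on_seam),
      class = "stripe_region")
  }
  if (!length(regions)) stop("no stripes found: all components touch the image border")
  regions <- regions[order(vapply(regions, function(r) r$centroid[["z"]], numeric(1)))]
  # drop the weaker of detections closer than min_separation along z
  keep <- rep(TRUE, length(regions))
  if (length(regions) > 1L) {
    for (k in 2L:length(regions)) {
      prev <- max(which(keep[seq_len(k - 1L)]))
      if (regions[[k]]$centroid[["z"]] - regions[[prev]]$centroid[["z"]] < min_separation) {
        if (regions[[k]]$peak_value > regions[[prev]]$peak_value) keep[prev] <- FALSE
        else keep[k] <- FALSE
      }
    }
  }
  regions[keep]
}

#' @export
print.stripe_region <- function(x, ...) {
  cat(sprintf("<stripe_region> centroid (u %.1f, z %.1f) mm | tilt %.3f deg | peak %.3g%s%s\n",
              x$centroid[["u"]], x$centroid[["z"]], x$tilt, x$peak_value,
              if (x$in_taper) " | in taper zone" else "",
              if (x$on_seam) " | on seam" else ""))
  invisible(x)
}

# perpendicular width of a stripe: its bounding-box z-extent minus the
# helical rise accumulated across its circumferential extent
stripe_width_est <- function(stripe) {
  rise <- (stripe$extent[["u_hi"]] - stripe$extent[["u_lo"]]) *
    tan(stripe$tilt * pi / 180)
  max(stripe$extent[["z_hi"]] - stripe$extent[["z_lo"]] - abs(rise), 1e-6)
}

#' Extract the profile perpendicular to a stripe
#'
#' Samples the image along the line through the stripe centroid
#' perpendicular to its fitted axis (bilinear interpolation, sample step of
#' half a pixel), averaging five parallel lines offset by -2..2 pixels along
#' the stripe axis to suppress noise.
#'
#' @param image A [stripe_image()] in exposure units.
#' @param stripe A `stripe_region` from [detect_stripes()].
#' @param length Profile length, mm; must span the stripe base plus
#'   background margins while staying inside the image.
#' @return A [dose_profile()] with axis `"perpendicular_to_stripe"`.
#' @export
extract_perpendicular_profile <- function(image, stripe, length) {
  stopifnot(inherits(image, "stripe_image"), inherits(stripe, "stripe_region"))
  if (image$units != "exposure")
    stop("extract_perpendicular_profile: image must be in exposure units")
  if (!is.finite(length) || length <= stripe_width_est(stripe))
    stop("extract_perpendicular_profile: profile length must exceed the stripe base")
  px <- image$pixel_spacing
  a <- stripe$tilt * pi / 180
  along <- c(cos(a), sin(a))        # (u, z) unit vector along the stripe
  perp <- c(-sin(a), cos(a))
  t <- seq(-length / 2, length / 2, by = px / 2)
  offs <- (-2:2) * px
  acc <- numeric(base::length(t))
  for (o in offs) {
    u <- stripe$centroid[["u"]] + o * along[1] + t * perp[1]
    z <- stripe$centroid[["z"]] + o * along[2] + t * perp[2]
    if (any(u < image$u_min + px / 2) ||
        any(u > image$u_min + ncol(image$data) * px - px / 2) ||
        any(z < image$z_min + px / 2) ||
        any(z > image$z_min + nrow(image$data) * px - px / 2))
      stop("extract_perpendicular_profile: profile window exits the image; ",
           "pick a stripe nearer the centre or a shorter length")
    acc <- acc + interp_bilinear(image, z, u)
  }
  dose_profile(acc / base::length(offs), px / 2, axis = "perpendicular_to_stripe",
               units = image$units, positions = t)
}

#' Longitudinal mean profile of a stripe image
#'
#' Places a rectangular region of interest (default: the whole image) and
#' averages along the circumferential direction for every z row, giving the
#' z dose profile whose FWTM is the actual exposure length.
#'
#' @param image A [stripe_image()] in exposure units.
#' @param roi Optional bounding box `list(z = c(lo, hi), u = c(lo, hi))` in
#'   mm; `NULL` uses the whole image.
#' @return A [dose_profile()] along z.
#' @export
z_profile <- function(image, roi = NULL) {
  stopifnot(inherits(image, "stripe_image"))
  d <- image$data
  zc <- z_coords(image)
  uc <- u_coords(image)
  rows <- seq_len(nrow(d))
  cols <- seq_len(ncol(d))
  if (!is.null(roi)) {
    if (!is.null(roi$z)) rows <- which(zc >= roi$z[1] & zc <= roi$z[2])
    if (!is.null(roi$u)) cols <- which(uc >= roi$u[1] & uc <= roi$u[2])
    if (!length(rows) || !length(cols)) stop("z_profile: empty ROI")
  }
  dose_profile(rowMeans(d[rows, cols, drop = FALSE]), image$pixel_spacing,
               axis = "z", units = image$units, positions = zc[rows])
}

#' Overranging from the actual exposure length
#'
#' `overranging = (FWTM - d) / 2`: the exposure extension beyond the planned
#' scan range at each end of the helical acquisition.
#'
#' @param fwtm Actual exposure length (FWTM of the z profile), mm.
#' @param scan_range_d Planned scan range d, mm.
#' @return Overranging per side, mm. Negative results (exposure shorter than
#'   the set range) are reported with a warning.
#' @examples
#' overranging(276.6, 160)  # 58.3
#' @export
overranging <- function(fwtm, scan_range_d) {
  if (!is.finite(fwtm) || !is.finite(scan_range_d))
    stop("overranging: inputs must be finite")
  if (fwtm < scan_range_d)
    warning("overranging: exposure length is shorter than the scan range; reporting a negative value")
  (fwtm - scan_range_d) / 2
}

#' Relative overranging reduction by the active collimator
#'
#' @param or_without Overranging without active collimation, mm (> 0).
#' @param or_with Overranging with active collimation, mm.
#' @return Reduction in percent.
#' @examples
#' reduction_ratio(58.3, 48.2)  # 17.32...
#' @export
reduction_ratio <- function(or_without, or_with) {
  if (!is.finite(or_without) || or_without <= 0)
    stop("reduction_ratio: overranging without collimation must be positive")
  if (!is.finite(or_with)) stop("reduction_ratio: or_with must be finite")
  100 * (or_without - or_with) / or_without
}

#' Overbeaming analysis of a stripe image
#'
#' Selects the `n_stripes` stripes nearest the middle of the scan range
#' (a deterministic stand-in for "arbitrary" stripes; taper-zone stripes are
#' excluded because the active collimator violates the full-aperture
#' assumption there), extracts the perpendicular profile of each, measures
#' its FWHM, magnifies it to the rotation centre and reports beam width and
#' dose efficiency as mean and SD over the stripes.
#'
#' @param image A [stripe_image()] in exposure units (stitched).
#' @param geometry A [scanner_geometry()].
#' @param nominal_bw Nominal collimation, mm.
#' @param n_stripes Number of stripes to measure (default 3). If fewer are
#'   available, all are analysed and the report is flagged.
#' @param profile_length Perpendicular profile length, mm; default 1.1 times
#'   the measured stripe spacing (or 3 times the stripe extent for a single
#'   stripe), keeping the background tails inside the inter-stripe gap.
#' @param smooth Optional odd moving-average width (samples) for the profiles.
#' @return A list with `beam_width` (mean, sd), `dose_efficiency` (mean,
#'   sd), per-stripe values and flags.
#' @export
analyze_overbeaming <- function(image, geometry, nominal_bw, n_stripes = 3,
                                profile_length = NULL, smooth = 0) {
  stopifnot(inherits(image, "stripe_image"), inherits(geometry, "scanner_geometry"))
  if (!is.finite(nominal_bw) || nominal_bw <= 0)
    stop("analyze_overbeaming: nominal_bw must be positive")
  regions <- detect_stripes(image)
  acq <- image$metadata$acquisition
  usable <- Filter(function(r) !r$in_taper, regions)
  if (!length(usable)) usable <- regions
  flags <- character()

  # with the active collimator, any stripe whose ridge lies within half a
  # beam base of a range boundary is blade-clipped and violates the
  # full-aperture assumption; estimate the half base from the stripe's own
  # plate-level width magnified to the isocenter
  if (!is.null(acq) && isTRUE(acq$active_collimator)) {
    clipped <- vapply(usable, function(r) {
      hb_est <- stripe_width_est(r) * geometry$fid / geometry$fsd / 2
      cz <- r$centroid[["z"]]
      cz < hb_est || cz > acq$scan_range_d - hb_est
    }, logical(1))
    if (any(!clipped)) {
      usable <- usable[!clipped]
    } else {
      flags <- c(flags, paste("all stripes lie in the collimator taper zones;",
                              "beam width may be underestimated"))
    }
  }

  zc <- vapply(usable, function(r) r$centroid[["z"]], numeric(1))
  spacing_est <- if (length(usable) > 1L) stats::median(diff(sort(zc)))
  else if (!is.null(acq))
    feed_per_rotation(acq$pitch, acq$nominal_collimation)
  else NA_real_

  # overlap guard: a single stripe spans at most one helical rise (the feed)
  # plus its own footprint, which separability bounds by another feed; merged
  # stripes form components spanning many feeds
  feed_ref <- if (!is.null(acq))
    feed_per_rotation(acq$pitch, acq$nominal_collimation) else spacing_est
  if (is.finite(feed_ref)) {
    tallest <- max(vapply(usable, function(r)
      r$extent[["z_hi"]] - r$extent[["z_lo"]], numeric(1)))
    if (tallest > 2.2 * feed_ref)
      stop("analyze_overbeaming: stripes overlap on the plate; ",
           "use a larger plate radius or a higher pitch")
  }

  if (length(usable) < n_stripes) {
    flags <- c(flags, sprintf("only %d usable stripe(s) for the requested %d",
                              length(usable), n_stripes))
    n_use <- length(usable)
  } else n_use <- n_stripes

  mid <- if (!is.null(acq)) acq$scan_range_d / 2 else stats::median(zc)
  sel <- usable[order(abs(zc - mid))][seq_len(n_use)]

  fwhm <- bw <- numeric(n_use)
  for (k in seq_len(n_use)) {
    L <- profile_length
    if (is.null(L)) {
      L <- if (is.finite(spacing_est)) 1.1 * spacing_est
      else 3 * stripe_width_est(sel[[k]])
    }
    prof <- extract_perpendicular_profile(image, sel[[k]], L)
    fwhm[k] <- measure_fwhm(prof, smooth = smooth)
    bw[k] <- correct_beam_width(fwhm[k], geometry)
  }
  # blade-clipped stripes sit near a range boundary and measure markedly
  # narrower than the widest (least clipped) stripe; the geometric pre-filter
  # above cannot catch them all because clipping also shrinks the apparent
  # stripe footprint it relies on
  if (!is.null(acq) && isTRUE(acq$active_collimator) && n_use > 1L) {
    ref <- max(bw)
    margin <- 0.55 * ref
    cz_sel <- vapply(sel, function(r) r$centroid[["z"]], numeric(1))
    clipped <- bw < 0.97 * ref &
      (cz_sel < margin | cz_sel > acq$scan_range_d - margin)
    if (any(clipped) && any(!clipped)) {
      flags <- c(flags, sprintf("dropped %d blade-clipped stripe(s) near the range boundaries",
                                sum(clipped)))
      sel <- sel[!clipped]; fwhm <- fwhm[!clipped]; bw <- bw[!clipped]
      n_use <- length(bw)
    }
  }
  de <- nominal_bw / bw
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  list(beam_width = c(mean = mean(bw), sd = sd0(bw)),
       dose_efficiency = c(mean = mean(de), sd = sd0(de)),
       fwhm_plate = fwhm, beam_width_per_stripe = bw,
       n_stripes = n_use, stripes = sel, flags = flags)
}

#' Overranging analysis of a stripe image
#'
#' Longitudinal mean profile over the whole image (or an ROI), FWTM as the
#' actual exposure length, and Eq.-style overranging against the planned
#' scan range.
#'
#' @param image A [stripe_image()] in exposure units.
#' @param acquisition An [acquisition_params()]; defaults to the acquisition
#'   stored in the image metadata.
#' @param roi Optional ROI passed to [z_profile()].
#' @param smooth Optional odd moving-average width (samples).
#' @return A list with `actual_exposure_length`, `overranging` (mm) and the
#'   measured `profile`.
#' @export
analyze_overranging <- function(image, acquisition = NULL, roi = NULL, smooth = 0) {
  stopifnot(inherits(image, "stripe_image"))
  if (image$units != "exposure")
    stop("analyze_overranging: convert the image to exposure units first (pv_to_exposure)")
  if (is.null(acquisition)) {
    am <- image$metadata$acquisition
    if (is.null(am))
      stop("analyze_overranging: no acquisition parameters given or stored in metadata")
    acquisition <- do.call(acquisition_params, am)
  }
  prof <- z_profile(image, roi)
  fwtm <- measure_fwtm(prof, smooth = smooth)
  list(actual_exposure_length = fwtm,
       overranging = overranging(fwtm, acquisition$scan_range_d),
       profile = prof)
}

#' Conventional flat-plate profile analysis
#'
#' Analysis mode for the conventional cross-check: a plate at the rotation
#' centre records the dose profile at unit magnification, so the FWHM is the
#' actual beam width directly (no magnification correction). With a scan
#' range given, the FWTM is the actual exposure length and overranging is
#' reported as well.
#'
#' @param profile A [dose_profile()] in exposure units.
#' @param geometry Unused; accepted for interface symmetry with the stripe
#'   analysis (the plate sits at the isocenter).
#' @param scan_range_d Optional planned scan range, mm.
#' @param smooth Optional odd moving-average width (samples).
#' @return A list with `beam_width` and, when `scan_range_d` is given,
#'   `actual_exposure_length` and `overranging`.
#' @export
analyze_flat_profile <- function(profile, geometry = NULL, scan_range_d = NULL,
                                 smooth = 0) {
  stopifnot(inherits(profile, "dose_profile"))
  out <- list(beam_width = measure_fwhm(profile, smooth = smooth))
  if (!is.null(scan_range_d)) {
    fwtm <- measure_fwtm(profile, smooth = smooth)
    out$actual_exposure_length <- fwtm
    out$overranging <- overranging(fwtm, scan_range_d)
  }
  out
}

#' Assemble a per-acquisition measurement report
#'
#' Collects the overbeaming and overranging results of one acquisition into
#' the tabular structure used by the CSV/JSON writers: collimation, pitch,
#' collimator state, beam width and dose efficiency (mean +/- SD over
#' stripes), exposure length, overranging, optional reduction ratio from a
#' paired run, and the console dose-length product carried as pass-through
#' metadata (never computed here).
#'
#' @param acquisition An [acquisition_params()].
#' @param overbeaming Result of [analyze_overbeaming()] (optional).
#' @param overranging_result Result of [analyze_overranging()] (optional).
#' @param reduction_ratio_percent Optional reduction ratio vs a paired run, %.
#' @param dlp_console Optional console-reported DLP, mGy cm (metadata only).
#' @return An object of class `measurement_report`.
#' @export
measurement_report <- function(acquisition, overbeaming = NULL,
                               overranging_result = NULL,
                               reduction_ratio_percent = NA_real_,
                               dlp_console = NA_real_) {
  stopifnot(inherits(acquisition, "acquisition_params"))
  structure(list(
    collimation = acquisition$nominal_collimation,
    pitch = acquisition$pitch,
    active_collimator = acquisition$active_collimator,
    bw_mean = if (is.null(overbeaming)) NA_real_ else overbeaming$beam_width[["mean"]],
    bw_sd = if (is.null(overbeaming)) NA_real_ else overbeaming$beam_width[["sd"]],
    de_mean = if (is.null(overbeaming)) NA_real_ else overbeaming$dose_efficiency[["mean"]],
    de_sd = if (is.null(overbeaming)) NA_real_ else overbeaming$dose_efficiency[["sd"]],
    exposure_length = if (is.null(overranging_result)) NA_real_
    else overranging_result$actual_exposure_length,
    overranging = if (is.null(overranging_result)) NA_real_
    else overranging_result$overranging,
    reduction_ratio = reduction_ratio_percent,
    dlp_console = dlp_console,
    flags = if (is.null(overbeaming)) character(0) else overbeaming$flags),
    class = "measurement_report")
}

# report rounding mirrors the conventions of CT QA tables:
# lengths to 0.1 mm, dose efficiency to 0.01, percentages to 0.1
rounded_report_fields <- function(r) {
  list(collimation = r$collimation, pitch = r$pitch,
       active_collimator = r$active_collimator,
       bw_mean = round(r$bw_mean, 1), bw_sd = round(r$bw_sd, 2),
       de_mean = round(r$de_mean, 2), de_sd = round(r$de_sd, 2),
       exposure_length = round(r$exposure_length, 1),
       overranging = round(r$overranging, 1),
       reduction_ratio = round(r$reduction_ratio, 1),
       dlp_console = r$dlp_console)
}

#' @export
print.measurement_report <- function(x, ...) {
  f <- rounded_report_fields(x)
  cat(sprintf("<measurement_report> collimation %.0f mm | pitch %.2f | active collimator %s\n",
              f$collimation, f$pitch, if (f$active_collimator) "on" else "off"))
  if (is.finite(x$bw_mean))
    cat(sprintf("  beam width %.1f +/- %.2f mm | dose efficiency %.2f +/- %.2f\n",
                f$bw_mean, f$bw_sd, f$de_mean, f$de_sd))
  if (is.finite(x$overranging))
    cat(sprintf("  exposure length %.1f mm | overranging %.1f mm\n",
                f$exposure_length, f$overranging))
  if (is.finite(x$reduction_ratio))
    cat(sprintf("  overranging reduction %.1f %%\n", f$reduction_ratio))
  if (is.finite(x$dlp_console))
    cat(sprintf("  console DLP (pass-through) %.1f mGy cm\n", x$dlp_console))
  for (fl in x$flags) cat("  flag:", fl, "\n")
  invisible(x)
}

#' @export
as.data.frame.measurement_report <- function(x, ...) {
  f <- rounded_report_fields(x)
  f$active_collimator <- as.logical(f$active_collimator)
  as.data.frame(f, stringsAsFactors = FALSE)
}
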