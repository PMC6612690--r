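#' Full width at a fractional maximum
#'
#' Shared engine for [measure_fwhm()] and [measure_fwtm()]. The background is
#' the mean of the outer 10% of samples on each tail; the level is
#' `background + frac * (peak - background)`. Crossing positions are found by
#' walking outwards from the global peak to the first sample below the level
#' and linearly interpolating between the bracketing samples.
#'
#' @param profile A [dose_profile()].
#' @param frac Fraction of the background-corrected maximum (0.5 or 0.1).
#' @param smooth Optional odd width (in samples) of a moving-average filter
#'   applied before measurement; 0 disables smoothing.
#' @return Width in mm.
#' @keywords internal
measure_width <- function(profile, frac, smooth = 0) {
  stopifnot(inherits(profile, "dose_profile"))
  v <- profile$values
  pos <- profile$positions
  if (smooth > 0) {
    if (smooth %% 2 == 0) stop("measure_width: smoothing width must be odd")
    v <- as.numeric(stats::filter(v, rep(1 / smooth, smooth), sides = 2))
    keep <- !is.na(v)
    v <- v[keep]; pos <- pos[keep]
  }
  n <- length(v)
  nt <- max(1L, floor(0.1 * n))
  background <- mean(c(v[seq_len(nt)], v[seq.int(n - nt + 1L, n)]))
  peak_i <- which.max(v)
  peak <- v[peak_i]
  if (peak <= background)
    stop("peak not resolved: profile has no peak above the tail background")
  level <- background + frac * (peak - background)

  below_left <- which(v[seq_len(peak_i)] < level)
  below_right <- which(v[seq.int(peak_i, n)] < level)
  if (length(below_left) == 0 || length(below_right) == 0)
    stop("peak not resolved: level not crossed on both flanks")
  li <- max(below_left)                       # v[li] < level <= v[li+1]
  ri <- peak_i + min(below_right) - 1L        # v[ri-1] >= level > v[ri]
  xl <- pos[li] + (pos[li + 1L] - pos[li]) * (level - v[li]) / (v[li + 1L] - v[li])
  xr <- pos[ri - 1L] + (pos[ri] - pos[ri - 1L]) * (level - v[ri - 1L]) / (v[ri] - v[ri - 1L])
  xr - xl
}

#' Full width at half maximum of a dose profile
#'
#' @inheritParams measure_width
#' @return FWHM in mm.
#' @examples
#' # triangle of base 10 mm: FWHM = 5 mm
#' z <- seq(-10, 10, by = 0.05)
#' p <- dose_profile(pmax(0, 1 - abs(z) / 5), 0.05, positions = z)
#' measure_fwhm(p)
#' @export
measure_fwhm <- function(profile, smooth = 0) measure_width(profile, 0.5, smooth)

#' Full width at tenth maximum of a dose profile
#'
#' The FWTM of the longitudinal mean profile is the actual exposure length of
#' a helical acquisition.
#'
#' @inheritParams measure_width
#' @return FWTM in mm.
#' @export
measure_fwtm <- function(profile, smooth = 0) measure_width(profile, 0.1, smooth)

#' Read a 1-D dose profile from delimited text
#'
#' Expects two columns, position (mm) and value, whitespace-, comma- or
#' tab-delimited, with `#` comments allowed. Sampling must be uniform.
#'
#' @param path File path.
#' @param units Units flag stored on the profile.
#' @return A [dose_profile()].
#' @export
read_profile_txt <- function(path, units = "exposure") {
  if (!file.exists(path)) stop("read_profile_txt: no such file: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           sep = "", col.names = c("position_mm", "value"),
                           colClasses = "numeric")
  if (nrow(tab) < 8) stop("read_profile_txt: need at least 8 samples")
  dpos <- diff(tab$position_mm)
  spacing <- stats::median(dpos)
  if (spacing <= 0 || any(abs(dpos - spacing) > 1e-6 * max(1, spacing)))
    stop("read_profile_txt: positions must be uniformly increasing")
  dose_profile(tab$value, spacing, axis = "z", units = units,
               positions = tab$position_mm)
}

#' Plot a dose profile with measured width levels
#'
#' Base-graphics plot of a profile with the background, half- and
#' tenth-maximum levels marked; used by the command-line `analyze` run to
#' document each measurement.
#'
#' @param profile A [dose_profile()].
#' @param main Plot title.
#' @export
plot_profile <- function(profile, main = "dose profile") {
  stopifnot(inherits(profile, "dose_profile"))
  v <- profile$values
  n <- length(v)
  nt <- max(1L, floor(0.1 * n))
  bg <- mean(c(v[seq_len(nt)], v[seq.int(n - nt + 1L, n)]))
  pk <- max(v)
  graphics::plot(profile$positions, v, type = "l",
                 xlab = sprintf("position along %s axis (mm)", profile$axis),
                 ylab = sprintf("intensity (%s)", profile$units), main = main)
  graphics::abline(h = bg + 0.5 * (pk - bg), lty = 2, col = "red")
  graphics::abline(h = bg + 0.1 * (pk - bg), lty = 3, col = "blue")
  graphics::abline(h = bg, lty = 1, col = "grey")
  graphics::legend("topright", lty = c(2, 3, 1),
                   col = c("red", "blue", "grey"), bty = "n", cex = 0.8,
                   legend = c("half maximum", "tenth maximum", "background"))
  invisible(profile)
}
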