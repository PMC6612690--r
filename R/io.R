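#' Write a stripe image as 16-bit TIFF plus JSON sidecar
#'
#' The canonical on-disk form is a 16-bit grayscale TIFF in PV units (the
#' 10--12-bit CR pixel values in a 16-bit container) with a JSON sidecar
#' carrying pixel spacing, units, axis conventions and all simulation or
#' acquisition metadata. Encode exposure images with [encode_pv()] first.
#'
#' @param image A [stripe_image()] in PV units.
#' @param path Output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return Invisibly, the two file paths.
#' @export
write_stripe_image <- function(image, path) {
  stopifnot(inherits(image, "stripe_image"))
  if (image$units != "PV")
    stop("write_stripe_image: encode the image to PV units first (encode_pv)")
  if (any(image$data < 0 | image$data > 65535))
    stop("write_stripe_image: PV out of the 16-bit range")
  tiff::writeTIFF(image$data / 65535, path, bits.per.sample = 16,
                  compression = "none")
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  side <- image$metadata
  side$pixel_spacing <- image$pixel_spacing
  side$units <- image$units
  side$z_min <- image$z_min
  side$u_min <- image$u_min
  side$dim <- dim(image$data)
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(image = path, sidecar = sidecar))
}

read_sidecar <- function(path) {
  if (!file.exists(path)) return(NULL)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a stripe image (or plate set) from disk
#'
#' Accepts 16-bit TIFF or PNG rasters with a JSON sidecar. Pixel spacing is
#' never guessed: it must come from the sidecar or the `pixel_spacing`
#' argument, otherwise reading fails. A vector of paths returns a
#' `plate_set` ordered by the sidecars' layout indices.
#'
#' @param path Path(s) to raster file(s).
#' @param sidecar_path Optional explicit sidecar path(s); default is the
#'   raster path with a `.json` extension.
#' @param pixel_spacing Fallback pixel spacing in mm when no sidecar exists.
#' @return A [stripe_image()] or a `plate_set`.
#' @export
read_image <- function(path, sidecar_path = NULL, pixel_spacing = NULL) {
  if (length(path) > 1L) {
    if (!is.null(sidecar_path) && length(sidecar_path) != length(path))
      stop("read_image: sidecar_path must match path in length")
    plates <- lapply(seq_along(path), function(k)
      read_image(path[k], sidecar_path[k], pixel_spacing))
    idx <- vapply(plates, function(p) {
      li <- p$metadata$plate$layout_index
      if (is.null(li)) NA_integer_ else as.integer(li)
    }, integer(1))
    if (!anyNA(idx)) plates <- plates[order(idx)]
    return(structure(plates, class = "plate_set"))
  }
  if (!file.exists(path)) stop("read_image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = {
                  if (!requireNamespace("png", quietly = TRUE))
                    stop("read_image: the png package is not installed")
                  png::readPNG(path)
                },
                stop("read_image: unsupported raster format: .", ext))
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  side <- read_sidecar(if (is.null(sidecar_path))
    paste0(tools::file_path_sans_ext(path), ".json") else sidecar_path)
  sp <- if (!is.null(side$pixel_spacing)) side$pixel_spacing else pixel_spacing
  if (is.null(sp))
    stop("read_image: pixel spacing unavailable for ", path,
         " (no sidecar and no pixel_spacing argument); it is never guessed")
  units <- if (!is.null(side$units)) side$units else "PV"
  data <- if (units == "PV") round(raw * 65535) else raw
  meta <- side
  meta$pixel_spacing <- NULL; meta$units <- NULL
  meta$z_min <- NULL; meta$u_min <- NULL; meta$dim <- NULL
  stripe_image(data, sp, units = units,
               z_min = if (!is.null(side$z_min)) side$z_min else 0,
               u_min = if (!is.null(side$u_min)) side$u_min else 0,
               metadata = if (is.null(meta)) list() else meta)
}

#' Write a plate set to disk
#'
#' Writes `<run_id>_plate<k>.tif` (+ sidecars) and `<run_id>_truth.json`.
#'
#' @param plates A `plate_set` in PV units.
#' @param outdir Output directory (created if needed).
#' @param run_id File-name prefix.
#' @param truth Optional `simulation_truth` to write alongside.
#' @return Invisibly, the written image paths.
#' @export
write_plate_set <- function(plates, outdir, run_id = "run", truth = NULL) {
  stopifnot(inherits(plates, "plate_set") || is.list(plates))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(plates))
  for (k in seq_along(plates)) {
    paths[k] <- file.path(outdir, sprintf("%s_plate%d.tif", run_id, k))
    write_stripe_image(plates[[k]], paths[k])
  }
  if (!is.null(truth))
    jsonlite::write_json(unclass(truth),
                         file.path(outdir, sprintf("%s_truth.json", run_id)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write measurement reports as JSON and CSV
#'
#' The CSV has one row per acquisition with the fixed column schema
#' (collimation, pitch, active_collimator, bw_mean, bw_sd, de_mean, de_sd,
#' exposure_length, overranging, reduction_ratio, dlp_console), rounded to
#' reporting precision; the JSON carries both the rounded and the raw
#' full-precision values.
#'
#' @param reports A `measurement_report` or list of them (may be empty).
#' @param path Output path without extension; `.json`/`.csv` are appended.
#' @param formats Subset of `c("json", "csv")`.
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(reports, path, formats = c("json", "csv")) {
  formats <- match.arg(formats, several.ok = TRUE)
  if (inherits(reports, "measurement_report")) reports <- list(reports)
  stopifnot(all(vapply(reports, inherits, logical(1), "measurement_report")))
  out <- character(0)
  schema <- c("collimation", "pitch", "active_collimator", "bw_mean", "bw_sd",
              "de_mean", "de_sd", "exposure_length", "overranging",
              "reduction_ratio", "dlp_console")
  if ("csv" %in% formats) {
    f <- paste0(path, ".csv")
    if (length(reports)) {
      tab <- do.call(rbind, lapply(reports, as.data.frame))
      utils::write.csv(tab[, schema], f, row.names = FALSE)
    } else {
      writeLines(paste(schema, collapse = ","), f)
    }
    out <- c(out, f)
  }
  if ("json" %in% formats) {
    f <- paste0(path, ".json")
    payload <- lapply(reports, function(r)
      list(raw = unclass(r), rounded = rounded_report_fields(r)))
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out <- c(out, f)
  }
  invisible(out)
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(sprintf("config: unknown key(s) in %s: %s (allowed: %s)",
                 where, paste(unknown, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  x
}

#' Read and validate a run configuration
#'
#' YAML or JSON (by extension) with blocks `geometry`, `acquisition`, `beam`
#' (simulation only), `grid` (simulation only), `analysis`, `io` and `seed`.
#' Field names match the constructor arguments exactly; unknown keys are
#' rejected with a clear error, and all sub-type invariants are validated
#' before any computation.
#'
#' @param path Config file path.
#' @return A list with validated `geometry`, `acquisition`, optional `beam`
#'   and `grid` objects, plus `analysis`, `io` and `seed` settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("read_run_config: unsupported config format: .", ext))
  check_keys(cfg, c("geometry", "acquisition", "beam", "grid", "analysis",
                    "io", "seed"), "top level")
  if (is.null(cfg$geometry) || is.null(cfg$acquisition))
    stop("config: geometry and acquisition blocks are required")
  geometry <- do.call(scanner_geometry,
                      check_keys(cfg$geometry,
                                 names(formals(scanner_geometry)), "geometry"))
  acquisition <- do.call(acquisition_params,
                         check_keys(cfg$acquisition,
                                    names(formals(acquisition_params)), "acquisition"))
  beam <- NULL
  if (!is.null(cfg$beam)) {
    bargs <- check_keys(cfg$beam, c("actual_bw_iso", "penumbra_iso",
                                    "fan_sigma_deg"), "beam")
    bargs$geometry <- geometry
    beam <- do.call(beam_model, bargs)
  }
  grid <- NULL
  if (!is.null(cfg$grid))
    grid <- do.call(grid_spec,
                    check_keys(cfg$grid, names(formals(grid_spec)), "grid"))
  analysis <- check_keys(
    if (is.null(cfg$analysis)) list() else cfg$analysis,
    c("n_stripes", "smooth", "gray_level", "noise_sd", "step_deg"), "analysis")
  if (is.null(analysis$n_stripes)) analysis$n_stripes <- 3
  if (is.null(analysis$smooth)) analysis$smooth <- 0
  if (is.null(analysis$gray_level)) analysis$gray_level <- 1024
  if (is.null(analysis$noise_sd)) analysis$noise_sd <- 0
  if (is.null(analysis$step_deg)) analysis$step_deg <- 0.5
  io <- check_keys(if (is.null(cfg$io)) list() else cfg$io,
                   c("run_id", "n_plates", "overlap_mm"), "io")
  if (is.null(io$run_id)) io$run_id <- "run"
  if (is.null(io$n_plates)) io$n_plates <- 5
  if (is.null(io$overlap_mm)) io$overlap_mm <- 0
  list(geometry = geometry, acquisition = acquisition, beam = beam,
       grid = grid, analysis = analysis, io = io, seed = cfg$seed)
}

#' Serialise geometry and acquisition back to a config block
#'
#' Writes the fully resolved configuration of a run next to its outputs so
#' the run can be reproduced bit-identically.
#'
#' @param config A list as returned by [read_run_config()].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) if (is.null(x)) NULL else unclass(x)
  g <- strip(config$geometry); g$fsd <- NULL
  out <- list(geometry = g,
              acquisition = strip(config$acquisition),
              beam = strip(config$beam),
              grid = strip(config$grid),
              analysis = config$analysis,
              io = config$io,
              seed = config$seed)
  out <- Filter(Negate(is.null), out)
  if (!is.null(out$grid)) out$grid <- Filter(Negate(is.null), out$grid)
  yaml::write_yaml(out, path)
  invisible(path)
}
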