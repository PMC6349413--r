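.spot_columns <- c("x_um", "y_um", "z_um", "weight", "L", "active")

#' Read or write a spot-target list
#'
#' CSV (header `x_um,y_um,z_um,weight,L,active`, comma-separated, '.'
#' decimal, UTF-8) or JSON (array of records with the same keys), mirroring
#' the coordinate table a user fills in per focal plane. `weight`, `L` and
#' `active` are optional on input and default to 1, 0 and true. Coordinates
#' are image-space micrometres: x rightward, y downward, z positive toward
#' the objective, origin at the holographic-FOV centre.
#'
#' @param path File ending in `.csv` or `.json`.
#' @return `read_spot_list` returns a [spot_targets()] table;
#'   `write_spot_list` returns `path` invisibly.
#' @export
read_spot_list <- function(path) {
  if (!file.exists(path)) stop("spot list not found: ", path)
  df <- switch(tolower(tools::file_ext(path)),
    "csv" = utils::read.csv(path, stringsAsFactors = FALSE),
    "json" = as.data.frame(
      jsonlite::read_json(path, simplifyVector = TRUE)),
    stop("unsupported spot-list format: ", path)
  )
  required <- c("x_um", "y_um", "z_um")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("spot list is missing required column(s): ",
         paste(missing, collapse = ", "))
  unknown <- setdiff(names(df), .spot_columns)
  if (length(unknown))
    stop("spot list has unknown column(s): ", paste(unknown, collapse = ", "))
  if (nrow(df) == 0L) stop("spot list is empty")
  spot_targets(
    x = df$x_um, y = df$y_um, z = df$z_um,
    weight = if ("weight" %in% names(df)) df$weight else 1,
    L = if ("L" %in% names(df)) df$L else 0L,
    active = if ("active" %in% names(df)) df$active else TRUE
  )
}

#' @rdname read_spot_list
#' @param spots A [spot_targets()] table.
#' @export
write_spot_list <- function(spots, path) {
  validate_spots(spots)
  df <- data.frame(x_um = spots$x, y_um = spots$y, z_um = spots$z,
                   weight = spots$weight, L = spots$L, active = spots$active)
  switch(tolower(tools::file_ext(path)),
    "csv" = utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    "json" = jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA),
    stop("unsupported spot-list format: ", path)
  )
  invisible(path)
}

# content hash of an R object via its canonical JSON serialization
object_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Write or read an 8-bit hologram image
#'
#' Single-channel 8-bit PNG or TIFF where grey level k encodes SLM phase
#' 2*pi*k/256, plus a JSON sidecar (`<path>.json`) recording the optics
#' configuration, its hash, and the final spot table the hologram encodes.
#'
#' @param hologram A `quantized_hologram` from [gen_hologram()].
#' @param path Output path ending in `.png` or `.tif`/`.tiff`.
#' @param config The [optics_config()] used (stored in the sidecar).
#' @return `write_hologram` returns `path` invisibly; `read_hologram`
#'   returns the `quantized_hologram`.
#' @export
write_hologram <- function(hologram, path, config = NULL) {
  stopifnot(inherits(hologram, "quantized_hologram"))
  img <- unclass(hologram) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "png" = png::writePNG(img, path),
    "tif" = ,
    "tiff" = tiff::writeTIFF(img, path, bits.per.sample = 8L,
                             compression = "none"),
    stop("unsupported hologram format: ", path)
  )
  sidecar <- list(levels = 256L, phase_per_level = 2 * pi / 256)
  if (!is.null(config)) {
    sidecar$config <- unclass(config)
    sidecar$config_hash <- object_hash(unclass(config))
  }
  spots <- attr(hologram, "spots")
  if (!is.null(spots)) sidecar$spots <- as.data.frame(spots)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hologram
#' @export
read_hologram <- function(path) {
  if (!file.exists(path)) stop("hologram file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "png" = png::readPNG(path),
    "tif" = ,
    "tiff" = tiff::readTIFF(path),
    stop("unsupported hologram format: ", path)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1]
  structure(matrix(as.integer(round(img * 255)), nrow(img), ncol(img)),
            class = "quantized_hologram")
}

#' Parse a z-plane range specification
#'
#' `"start:stop:step"` in micrometres expands to
#' `seq(start, stop, by = step)`; `"0:0:1"` gives the single plane 0.
#'
#' @param z_spec Character scalar.
#' @return Numeric vector of z-planes.
#' @export
#' @examples
#' parse_z_spec("-5:5:5")   # -5 0 5
parse_z_spec <- function(z_spec) {
  parts <- strsplit(z_spec, ":", fixed = TRUE)[[1]]
  vals <- suppressWarnings(as.numeric(parts))
  if (length(vals) != 3L || any(is.na(vals)))
    stop("malformed z specification (expected start:stop:step in um): ",
         z_spec)
  if (vals[3] <= 0) stop("z step must be positive: ", z_spec)
  if (vals[2] < vals[1]) stop("z stop must be >= start: ", z_spec)
  seq(vals[1], vals[2], by = vals[3])
}

#' Hologram generation run (CLI backend)
#'
#' Reads a spot list and optics configuration, synthesizes the hologram
#' (optionally with inverse amplitude weighting and parking), and writes the
#' 8-bit image plus sidecar. Identical inputs produce byte-identical
#' outputs.
#'
#' @param spot_list_path CSV/JSON spot list ([read_spot_list()]).
#' @param config_path YAML/JSON optics configuration
#'   ([read_optics_config()]).
#' @param out_path Output image path (`.png`/`.tif`).
#' @param weighting,n_active Passed to [gen_hologram()].
#' @return `out_path`, invisibly.
#' @export
run_gen <- function(spot_list_path, config_path, out_path,
                    weighting = FALSE, n_active = NULL) {
  spots <- read_spot_list(spot_list_path)
  config <- read_optics_config(config_path)
  holo <- gen_hologram(spots, config, weighting = weighting,
                       n_active = n_active)
  write_hologram(holo, out_path, config = config)
  message(sprintf("hologram %dx%d written to %s (config hash %s)",
                  nrow(holo), ncol(holo), out_path,
                  object_hash(unclass(config))))
  invisible(out_path)
}

#' Propagation run (CLI backend)
#'
#' Reads a stored hologram and configuration, simulates the intensity and
#' two-photon volumes over the requested z-planes, and writes both as
#' multi-page 32-bit TIFF with sidecars (`<out>.tif`, `<out>_2p.tif`).
#'
#' @param hologram_path 8-bit hologram image ([read_hologram()]).
#' @param config_path Optics configuration file.
#' @param z_spec `"start:stop:step"` z-planes, micrometres.
#' @param out_path Output TIFF path for the intensity volume.
#' @param aperture Apply the holographic-FOV aperture window.
#' @return `out_path`, invisibly.
#' @export
run_simulate <- function(hologram_path, config_path, z_spec, out_path,
                         aperture = FALSE) {
  holo <- read_hologram(hologram_path)
  config <- read_optics_config(config_path)
  vol <- propagate(holo, config, z_planes = parse_z_spec(z_spec))
  if (aperture) vol <- apply_aperture(vol, config)
  write_volume_tiff(vol, out_path)
  two_p <- paste0(sub("\\.tiff?$", "", out_path), "_2p.tif")
  write_volume_tiff(two_photon_volume(vol), two_p)
  message(sprintf("volumes written to %s and %s", out_path, two_p))
  invisible(out_path)
}

#' Characterization run (CLI backend)
#'
#' Reads a simulated (or fixture) volume and a spot list, measures per-spot
#' power and the lateral/axial FWHM at the brightest focus, and writes a CSV
#' report plus a JSON summary.
#'
#' @param volume_path Multi-page TIFF volume ([read_volume_tiff()]).
#' @param spots_path Spot list file.
#' @param out_path Output CSV path (a `.json` summary is written alongside).
#' @param radius Integration radius in micrometres (default: see
#'   [per_spot_power()]).
#' @return Data frame of the per-spot report, invisibly.
#' @export
run_characterize <- function(volume_path, spots_path, out_path,
                             radius = NULL) {
  vol <- read_volume_tiff(volume_path)
  spots <- read_spot_list(spots_path)
  report <- per_spot_power(vol, spots, radius = radius)
  fwhm_x <- tryCatch({
    pr <- peak_profile(vol, "x")
    measure_fwhm(pr$values, pr$spacing)
  }, error = function(e) NA_real_)
  fwhm_z <- tryCatch({
    pr <- peak_profile(vol, "z")
    measure_fwhm(pr$values, pr$spacing)
  }, error = function(e) NA_real_)
  utils::write.csv(report, out_path, row.names = FALSE)
  summary <- list(n_spots = nrow(report),
                  total_power = sum(report$power),
                  fwhm_lateral_um = fwhm_x,
                  fwhm_axial_um = fwhm_z)
  jsonlite::write_json(summary, paste0(sub("\\.csv$", "", out_path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
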