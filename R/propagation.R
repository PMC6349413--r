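# Swap quadrants so the grid centre (index n %/% 2 + 1) moves to index 1
# (inverse = FALSE is fftshift, TRUE is ifftshift; identical for even sizes).
fftshift_mat <- function(m, inverse = FALSE) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- if (inverse) n1 %/% 2L else (n1 + 1L) %/% 2L
  s2 <- if (inverse) n2 %/% 2L else (n2 + 1L) %/% 2L
  m[c((s1 + 1L):n1, 1L:s1), c((s2 + 1L):n2, 1L:s2), drop = FALSE]
}

#' Simulated 3D intensity volume
#'
#' Container for a simulated intensity (or two-photon signal) stack:
#' non-negative voxel values on a regular lateral grid at a set of z-planes,
#' with coordinates in image-space micrometres (x rightward along columns, y
#' downward along rows, origin at the holographic-FOV centre).
#'
#' @param values 3D array, `length(y)` x `length(x)` x `length(z)`.
#' @param x,y,z Voxel-centre coordinate vectors in micrometres.
#' @return Object of class `intensity_volume` with fields `values`, `x`, `y`,
#'   `z` and `voxel_size` `(dy, dx, dz)` (`dz` is `NA` for a single plane or
#'   irregular z-spacing).
#' @export
intensity_volume <- function(values, x, y, z) {
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  stopifnot(length(dim(values)) == 3L,
            dim(values)[1] == length(y),
            dim(values)[2] == length(x),
            dim(values)[3] == length(z))
  if (any(values < 0)) stop("intensity values must be non-negative")
  dz <- if (length(z) > 1L) {
    dd <- diff(z)
    if (max(abs(dd - dd[1])) < 1e-9) dd[1] else NA_real_
  } else NA_real_
  structure(list(values = values, x = x, y = y, z = z,
                 voxel_size = c(dy = if (length(y) > 1) y[2] - y[1] else NA_real_,
                                dx = if (length(x) > 1) x[2] - x[1] else NA_real_,
                                dz = dz)),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<intensity_volume> %d x %d x %d planes, dx %.4g um, peak %.4g\n",
              d[1], d[2], d[3], x$voxel_size["dx"], max(x$values)))
  cat(sprintf("  x [%.2f, %.2f] um, y [%.2f, %.2f] um, z {%s} um\n",
              min(x$x), max(x$x), min(x$y), max(x$y),
              paste(format(x$z, digits = 3), collapse = ", ")))
  invisible(x)
}

#' Propagate a pupil phase map to a 3D intensity volume
#'
#' Scalar Fourier-optics oracle for the projector. For each requested
#' z-plane, the unit-amplitude pupil field `exp(i * phase)` is apodized by
#' the pupil disk, multiplied by the paraxial defocus factor that cancels the
#' hologram's lens phase at the target plane (`exp(-2 pi i gamma rho^2 z)`,
#' with the same scaling factor gamma used for hologram synthesis),
#' zero-padded by `pad_factor`, and Fourier-transformed; intensity is the
#' squared modulus. The image-plane sample spacing is
#' `2 * dx_max / (pad_factor * slm_pixels)` and the image covers the full
#' holographic FOV `[-dx_max, dx_max)`. The transform is unitary, so before
#' the envelope the total image energy equals the pupil energy (Parseval).
#' The pixel-footprint sinc-squared envelope is then applied multiplicatively
#' in the image plane (equivalent, by the array theorem, to unit-fill-factor
#' SLM pixels).
#'
#' @param phase A `phase_map` or `quantized_hologram` of size
#'   `slm_pixels` x `slm_pixels`.
#' @param config An [optics_config()].
#' @param z_planes Numeric vector of z-planes (micrometres) to evaluate.
#' @param envelope Apply the lateral sinc-squared efficiency envelope
#'   (default `TRUE`).
#' @param aberration Optional pupil-phase surface (radians, e.g. from
#'   [zernike_surface()]) added to the hologram phase, modelling a system
#'   aberration the hologram did not ask for.
#' @return An [intensity_volume()].
#' @export
#' @examples
#' cfg <- optics_config(slm_pixels = 128)
#' holo <- gen_hologram(spot_targets(x = 5), cfg)
#' vol <- propagate(holo, cfg, z_planes = 0)
propagate <- function(phase, config, z_planes, envelope = TRUE,
                      aberration = NULL) {
  stopifnot(inherits(config, "optics_config"))
  if (length(z_planes) == 0L || any(!is.finite(z_planes)))
    stop("`z_planes` must be a non-empty vector of finite z positions (um)")
  if (inherits(phase, "quantized_hologram")) phase <- dequantize_phase(phase)
  n <- config$slm_pixels
  if (!all(dim(phase) == c(n, n)))
    stop("phase map size does not match config$slm_pixels")

  g <- pupil_grid(n)
  ph <- unclass(phase)
  if (!is.null(aberration)) {
    stopifnot(all(dim(aberration) == c(n, n)))
    ph <- ph + aberration
  }
  pupil <- exp(1i * ph)
  pupil[!g$mask] <- 0i
  rho2 <- g$u^2 + g$v^2

  m <- config$pad_factor * n
  dx_max <- fov_half_range(config$wavelength, n, config$numerical_aperture)
  dxi <- 2 * dx_max / m
  coords <- (seq_len(m) - 1 - m %/% 2) * dxi
  off <- m %/% 2 - n %/% 2
  env2d <- if (envelope)
    outer(sinc(pi * coords / (2 * dx_max))^2,
          sinc(pi * coords / (2 * dx_max))^2)

  vol <- array(0, dim = c(m, m, length(z_planes)))
  for (k in seq_along(z_planes)) {
    field <- pupil * exp(-2i * pi * config$defocus_scale * rho2 * z_planes[k])
    padded <- matrix(0i, m, m)
    padded[off + seq_len(n), off + seq_len(n)] <- field
    img <- fftshift_mat(stats::fft(fftshift_mat(padded, inverse = TRUE))) / m
    intensity <- Mod(img)^2
    if (envelope) intensity <- intensity * env2d
    vol[, , k] <- intensity
  }
  out <- intensity_volume(vol, x = coords, y = coords, z = z_planes)
  attr(out, "config") <- config
  out
}

#' Clip a volume by the holographic-FOV aperture window
#'
#' Beyond a certain lateral deviation the steered beam falls off the relay
#' optics between the SLM and the scanning mirrors; this is modelled as a
#' hard square transmission window of half-width `fov_aperture_halfwidth`
#' centred on the holographic-FOV centre. Intensity outside the window is
#' set to zero; parked spots sit outside it by construction and so deliver
#' nothing.
#'
#' @param volume An [intensity_volume()].
#' @param config An [optics_config()] providing the half-width, or `NULL`
#'   when `halfwidth` is given directly.
#' @param halfwidth Window half-width in micrometres (`Inf` for no clipping).
#' @return The clipped volume.
#' @export
apply_aperture <- function(volume, config = NULL,
                           halfwidth = config$fov_aperture_halfwidth) {
  stopifnot(inherits(volume, "intensity_volume"))
  if (is.null(halfwidth) || !is.numeric(halfwidth) || halfwidth <= 0)
    stop("aperture half-width must be positive")
  if (is.finite(halfwidth)) {
    outside_y <- abs(volume$y) > halfwidth
    outside_x <- abs(volume$x) > halfwidth
    volume$values[outside_y, , ] <- 0
    volume$values[, outside_x, ] <- 0
  }
  volume
}

#' Two-photon signal volume
#'
#' Two-photon excitation is a nonlinear process: the fluorescence (or
#' photolysis) signal is proportional to the square of the excitation
#' intensity, which confines excitation to the focal volume. Squares the
#' voxel values element-wise, preserving coordinates.
#'
#' @param volume An [intensity_volume()] of excitation intensity.
#' @return An [intensity_volume()] of two-photon signal.
#' @export
two_photon_volume <- function(volume) {
  stopifnot(inherits(volume, "intensity_volume"))
  volume$values <- volume$values^2
  volume
}

#' Read or write an intensity volume as multi-page TIFF
#'
#' One 32-bit float page per z-plane plus a JSON sidecar (`<path>.json`)
#' recording voxel sizes, coordinate origin, z-planes, and the scale factor
#' used to map intensities into the TIFF's unit range.
#'
#' @param volume An [intensity_volume()].
#' @param path Output TIFF path.
#' @return `write_volume_tiff` returns `path` invisibly; `read_volume_tiff`
#'   returns the reconstructed [intensity_volume()].
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "intensity_volume"))
  peak <- max(volume$values)
  scale <- if (peak > 0) peak else 1
  pages <- lapply(seq_along(volume$z),
                  function(k) volume$values[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  sidecar <- list(voxel_size = as.list(volume$voxel_size),
                  origin = c(x = volume$x[1], y = volume$y[1], z = volume$z[1]),
                  x = volume$x, y = volume$y, z = volume$z,
                  intensity_scale = scale)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing volume sidecar: ", sidecar_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  vals <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) vals[, , k] <- pages[[k]] * meta$intensity_scale
  intensity_volume(vals, x = meta$x, y = meta$y, z = meta$z)
}
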