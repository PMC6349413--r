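#' Optical configuration of the holographic projector
#'
#' Bundles the physical parameters of the SLM-based projector: excitation
#' wavelength, objective numerical aperture, SLM working-area geometry, the
#' prism/lens scaling factors of the hologram equation, the diffraction
#' efficiency envelope parameters, and the relay-optics aperture that bounds
#' the usable holographic field of view (FOV).
#'
#' The hologram phase for spot \eqn{n} at \eqn{(x_n, y_n, z_n)} is
#' \deqn{2\pi[\alpha u x_n + \beta v y_n + \gamma (u^2+v^2) z_n] + \sum C_q^p Z_q^p(u,v),}
#' with pupil coordinates \eqn{(u, v)} normalized so the pupil-edge radius is 1.
#' Under that convention the physical defaults are \eqn{\alpha = \beta =
#' \mathrm{NA}/\lambda} (Abbe-sine lateral shift) and \eqn{\gamma =
#' -\mathrm{NA}^2 / (2 n \lambda)} (paraxial defocus). The scaling factors are
#' stored mutable because in practice they absorb calibration adjustments.
#'
#' @param wavelength Excitation wavelength in micrometres (default 0.75, the
#'   uncaging wavelength).
#' @param numerical_aperture Objective NA (dimensionless).
#' @param immersion_index Refractive index of the immersion medium (water,
#'   1.33).
#' @param slm_pixels Pixel count of the square SLM working area.
#' @param slm_pitch SLM pixel pitch in micrometres.
#' @param scale_x,scale_y Prism scaling factors \eqn{\alpha}, \eqn{\beta} in
#'   cycles per (normalized-pupil-unit x micrometre); default NA/wavelength.
#' @param defocus_scale Lens scaling factor \eqn{\gamma} in cycles per
#'   (normalized-pupil-unit^2 x micrometre); default
#'   \code{-NA^2/(2 * immersion_index * wavelength)}.
#' @param axial_sigma Width (micrometres) of the empirical Gaussian model of
#'   the axial diffraction-efficiency decline.
#' @param fov_aperture_halfwidth Half-width (micrometres) of the hard square
#'   transmission window modelling beam fall-off at the relay lenses;
#'   objective-dependent (35 for the 20x profile, 15 for 60x).
#' @param pad_factor Integer FFT zero-padding factor controlling image-plane
#'   sampling in [propagate()].
#'
#' @return An object of class `optics_config`.
#' @seealso [fov_half_range()], [envelope_model()], [propagate()]
#' @export
#' @examples
#' cfg <- optics_config()
#' cfg$scale_x              # NA / lambda
#' fov_half_range(cfg$wavelength, cfg$slm_pixels, cfg$numerical_aperture)
optics_config <- function(wavelength = 0.75,
                          numerical_aperture = 1.0,
                          immersion_index = 1.33,
                          slm_pixels = 600L,
                          slm_pitch = 20,
                          scale_x = NULL,
                          scale_y = NULL,
                          defocus_scale = NULL,
                          axial_sigma = 50,
                          fov_aperture_halfwidth = 35,
                          pad_factor = 2L) {
  if (!is.numeric(wavelength) || length(wavelength) != 1L || wavelength <= 0)
    stop("`wavelength` must be a single positive number (micrometres)")
  if (!is.numeric(numerical_aperture) || numerical_aperture <= 0 ||
      numerical_aperture > immersion_index)
    stop("`numerical_aperture` must satisfy 0 < NA <= immersion_index")
  slm_pixels <- as.integer(slm_pixels)
  if (is.na(slm_pixels) || slm_pixels < 2L)
    stop("`slm_pixels` must be an integer >= 2")
  if (slm_pitch <= 0) stop("`slm_pitch` must be positive")
  if (axial_sigma <= 0) stop("`axial_sigma` must be positive")
  if (fov_aperture_halfwidth <= 0)
    stop("`fov_aperture_halfwidth` must be positive")
  pad_factor <- as.integer(pad_factor)
  if (is.na(pad_factor) || pad_factor < 1L)
    stop("`pad_factor` must be an integer >= 1")

  if (is.null(scale_x)) scale_x <- numerical_aperture / wavelength
  if (is.null(scale_y)) scale_y <- numerical_aperture / wavelength
  if (is.null(defocus_scale))
    defocus_scale <- -numerical_aperture^2 / (2 * immersion_index * wavelength)
  stopifnot(is.finite(scale_x), is.finite(scale_y), is.finite(defocus_scale))

  structure(
    list(
      wavelength = wavelength,
      numerical_aperture = numerical_aperture,
      immersion_index = immersion_index,
      slm_pixels = slm_pixels,
      slm_pitch = slm_pitch,
      scale_x = scale_x,
      scale_y = scale_y,
      defocus_scale = defocus_scale,
      axial_sigma = axial_sigma,
      fov_aperture_halfwidth = fov_aperture_halfwidth,
      pad_factor = pad_factor
    ),
    class = "optics_config"
  )
}

#' @export
print.optics_config <- function(x, ...) {
  dx <- fov_half_range(x$wavelength, x$slm_pixels, x$numerical_aperture)
  cat("<optics_config>\n")
  cat(sprintf("  wavelength           %.3f um\n", x$wavelength))
  cat(sprintf("  NA / immersion n     %.2f / %.2f\n",
              x$numerical_aperture, x$immersion_index))
  cat(sprintf("  SLM                  %d x %d px, pitch %.1f um\n",
              x$slm_pixels, x$slm_pixels, x$slm_pitch))
  cat(sprintf("  alpha, beta, gamma   %.4g, %.4g, %.4g\n",
              x$scale_x, x$scale_y, x$defocus_scale))
  cat(sprintf("  holographic FOV      %.1f x %.1f um (2 dx_max)\n", 2 * dx, 2 * dx))
  cat(sprintf("  aperture half-width  %.1f um, axial sigma %.1f um\n",
              x$fov_aperture_halfwidth, x$axial_sigma))
  cat(sprintf("  pad_factor           %d\n", x$pad_factor))
  invisible(x)
}

#' Space-bandwidth half-range of the holographic FOV
#'
#' The lateral half-range over which first-order holographic foci can be
#' steered when the SLM image fills the objective back aperture:
#' \deqn{dx_{max} = \lambda N_{pix} / (4\,\mathrm{NA}).}
#' The full holographic FOV is a square of side `2 * dx_max`.
#'
#' @param wavelength Wavelength in micrometres.
#' @param n_pix SLM pixel count along one side of the working area.
#' @param numerical_aperture Objective NA.
#' @return Half-range in micrometres.
#' @export
#' @examples
#' fov_half_range(0.75, 600, 1.0)  # 112.5 um, i.e. a 225 um full side
fov_half_range <- function(wavelength, n_pix, numerical_aperture) {
  if (any(c(wavelength, n_pix, numerical_aperture) <= 0) ||
      !all(is.finite(c(wavelength, n_pix, numerical_aperture))))
    stop("all arguments to `fov_half_range` must be positive and finite")
  wavelength * n_pix / (4 * numerical_aperture)
}

# unnormalized mathematical sinc, sin(t)/t with sinc(0) = 1
sinc <- function(t) {
  out <- rep(1, length(t))
  nz <- t != 0
  out[nz] <- sin(t[nz]) / t[nz]
  if (!is.null(dim(t))) dim(out) <- dim(t)
  out
}

#' Lateral diffraction-efficiency envelope
#'
#' First-order spot intensity declines with lateral displacement because the
#' SLM is pixelated; the finite pixel footprint imposes a separable
#' sinc-squared envelope
#' \deqn{\eta(x, y) = \mathrm{sinc}^2\!\big(\pi x / (2 dx_{max})\big)\,
#'                    \mathrm{sinc}^2\!\big(\pi y / (2 dx_{max})\big)}
#' with the unnormalized convention \eqn{\mathrm{sinc}(t) = \sin(t)/t}. At the
#' Nyquist displacement \eqn{x = dx_{max}} the efficiency is exactly
#' \eqn{(2/\pi)^2 \approx 0.405}.
#'
#' @param x,y Lateral displacement from the FOV centre, micrometres
#'   (vectorized).
#' @param dx_max Holographic half-range from [fov_half_range()].
#' @return Efficiency fraction in (0, 1].
#' @export
lateral_efficiency <- function(x, y, dx_max) {
  if (!is.numeric(dx_max) || length(dx_max) != 1L || dx_max <= 0)
    stop("`dx_max` must be a single positive number")
  sinc(pi * x / (2 * dx_max))^2 * sinc(pi * y / (2 * dx_max))^2
}

#' Axial diffraction-efficiency envelope
#'
#' Delivered power also declines with axial (defocus) displacement of a
#' holographic focus; this hardware effect is modelled by the empirical
#' Gaussian \eqn{\eta(z) = \exp(-z^2 / (2\sigma_z^2))} used for amplitude
#' weighting.
#'
#' @param z Axial displacement in micrometres (vectorized).
#' @param axial_sigma Gaussian width \eqn{\sigma_z} in micrometres.
#' @return Efficiency fraction in (0, 1].
#' @export
axial_efficiency <- function(z, axial_sigma) {
  if (!is.numeric(axial_sigma) || length(axial_sigma) != 1L || axial_sigma <= 0)
    stop("`axial_sigma` must be a single positive number")
  exp(-z^2 / (2 * axial_sigma^2))
}

#' Diffraction-efficiency envelope model
#'
#' Combines the lateral sinc-squared and axial Gaussian efficiency envelopes
#' with a cap on the inverse amplitude-weighting gain, for use by
#' [compute_amplitude_weights()].
#'
#' @param dx_max Lateral half-range (micrometres), from [fov_half_range()].
#' @param axial_sigma Axial Gaussian width (micrometres).
#' @param max_gain Cap on the inverse-weighting amplitude gain (>= 1).
#' @return An object of class `envelope_model`.
#' @export
envelope_model <- function(dx_max, axial_sigma, max_gain = 4) {
  if (dx_max <= 0) stop("`dx_max` must be positive")
  if (axial_sigma <= 0) stop("`axial_sigma` must be positive")
  if (max_gain < 1) stop("`max_gain` must be >= 1")
  structure(list(dx_max = dx_max, axial_sigma = axial_sigma,
                 max_gain = max_gain),
            class = "envelope_model")
}

#' @rdname envelope_model
#' @param config An [optics_config()].
#' @export
envelope_from_config <- function(config, max_gain = 4) {
  stopifnot(inherits(config, "optics_config"))
  envelope_model(
    dx_max = fov_half_range(config$wavelength, config$slm_pixels,
                            config$numerical_aperture),
    axial_sigma = config$axial_sigma,
    max_gain = max_gain
  )
}

#' @export
print.envelope_model <- function(x, ...) {
  cat(sprintf(
    "<envelope_model> dx_max %.1f um, axial sigma %.1f um, max gain %.1f\n",
    x$dx_max, x$axial_sigma, x$max_gain))
  invisible(x)
}

.config_fields <- c("wavelength", "numerical_aperture", "immersion_index",
                    "slm_pixels", "slm_pitch", "scale_x", "scale_y",
                    "defocus_scale", "axial_sigma", "fov_aperture_halfwidth",
                    "pad_factor")

#' Read or write an optics configuration file
#'
#' Flat YAML or JSON (chosen by file extension) with one key per
#' [optics_config()] field, in the units documented there. Unknown keys are
#' rejected so silent typos cannot change the optics.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_optics_config` returns an `optics_config`;
#'   `write_optics_config` returns `path` invisibly.
#' @export
read_optics_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- switch(tolower(tools::file_ext(path)),
    "yaml" = ,
    "yml"  = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: ", path)
  )
  unknown <- setdiff(names(vals), .config_fields)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(optics_config, vals)
}

#' @rdname read_optics_config
#' @param config An [optics_config()].
#' @export
write_optics_config <- function(config, path) {
  stopifnot(inherits(config, "optics_config"))
  vals <- unclass(config)
  switch(tolower(tools::file_ext(path)),
    "yaml" = ,
    "yml"  = yaml::write_yaml(vals, path, precision = 15L),
    "json" = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported config format: ", path)
  )
  invisible(path)
}
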