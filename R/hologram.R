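#' Stimulation spot targets
#'
#' A table of holographic foci: image-space position (micrometres, x
#' rightward, y downward, z positive toward the objective, origin at the
#' holographic-FOV centre), amplitude weight \eqn{A_n}, optional
#' Laguerre-Gaussian vortex charge `L` (used to align the SLM centre: a
#' charged beam focuses to a ring with a dark core on the optical axis), an
#' `active` flag (inactive spots contribute nothing to the hologram) and a
#' `parked` flag set by [park_spots()].
#'
#' @param x,y,z Coordinates in micrometres (recycled to common length).
#' @param weight Non-negative amplitude weights, default 1.
#' @param L Integer vortex charges, default 0.
#' @param active Logical, default `TRUE`.
#' @param phase Per-spot phase offset in radians (the free phase of the
#'   complex amplitude \eqn{A_n}). The default `NA` assigns each spot a
#'   fixed pseudo-random offset by its position in the list (see
#'   [superpose_field()]); set explicit values (e.g. 0) to control the
#'   offsets directly.
#' @return Object of class `spot_targets` (a data frame).
#' @export
#' @examples
#' spot_targets(x = c(-5, 5), y = 0, z = c(0, 3))
spot_targets <- function(x, y = 0, z = 0, weight = 1, L = 0L, active = TRUE,
                         phase = NA_real_) {
  n <- max(length(x), length(y), length(z))
  df <- data.frame(
    x = rep_len(as.numeric(x), n),
    y = rep_len(as.numeric(y), n),
    z = rep_len(as.numeric(z), n),
    weight = rep_len(as.numeric(weight), n),
    L = rep_len(as.integer(L), n),
    active = rep_len(as.logical(active), n),
    parked = rep_len(FALSE, n),
    phase = rep_len(as.numeric(phase), n)
  )
  validate_spots(df)
  structure(df, class = c("spot_targets", "data.frame"))
}

validate_spots <- function(spots) {
  if (!all(is.finite(spots$x), is.finite(spots$y), is.finite(spots$z)))
    stop("spot coordinates must be finite")
  if (any(!is.finite(spots$weight)) || any(spots$weight < 0))
    stop("spot weights must be finite and >= 0")
  invisible(spots)
}

# Fixed pseudo-random per-spot phase table (uniform on [0, 2*pi), frozen
# stream) indexed by position in the spot list, so holograms remain pure
# functions of their inputs while unresolved (NA) offsets decorrelate the
# inter-spot interference.
spot_phase_table <- function(n) {
  with_seed(1L, stats::runif(n, 0, 2 * pi))
}

resolve_spot_phases <- function(spots) {
  if (is.null(spots$phase)) spots$phase <- NA_real_
  nas <- is.na(spots$phase)
  if (any(nas)) spots$phase[nas] <- spot_phase_table(nrow(spots))[nas]
  spots
}

#' @export
print.spot_targets <- function(x, ...) {
  cat(sprintf("<spot_targets> %d spot(s), %d active, %d parked\n",
              nrow(x), sum(x$active), sum(x$parked)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Superpose the complex pupil field for a spot list
#'
#' Prism-lens superposition: each active spot \eqn{n} contributes
#' \deqn{A_n \exp\!\big(2\pi i[\alpha u x_n + \beta v y_n +
#'   \gamma(u^2+v^2) z_n] + i\textstyle\sum C_q^p Z_q^p(u,v) + i L_n \theta\big)}
#' on the normalized pupil grid; the total field is the element-wise sum.
#' The linear (prism) term steers the focus laterally, the quadratic (lens)
#' term axially, the Zernike sum pre-compensates aberrations, and the
#' azimuthal term encodes an optional vortex charge.
#'
#' Each complex amplitude additionally carries the spot's free phase offset
#' (`phase` column): an offset changes nothing about a focus's position or
#' intensity in the ideal superposition, but after phase-only extraction
#' identical offsets let the inter-spot interference pile into ghost orders.
#' Spots with `phase = NA` (the default) therefore receive a fixed
#' pseudo-random offset by list position — the standard random-superposition
#' refinement of the prism-lens algorithm, kept deterministic here.
#'
#' @param spots A [spot_targets()] table with at least one active spot of
#'   positive weight.
#' @param config An [optics_config()].
#' @param zernike A [zernike_spec()] applied to every spot (global scope), or
#'   a list of specs, one per spot (per-spot scope, e.g. depth-dependent
#'   corrections), or `NULL`.
#' @return Complex matrix `slm_pixels` x `slm_pixels`.
#' @export
superpose_field <- function(spots, config, zernike = NULL) {
  stopifnot(inherits(config, "optics_config"))
  validate_spots(spots)
  act <- which(spots$active & spots$weight > 0)
  if (length(act) == 0L)
    stop("no active spot with positive weight: nothing to superpose")
  spots <- resolve_spot_phases(spots)
  g <- pupil_grid(config$slm_pixels)
  rho2 <- g$u^2 + g$v^2

  per_spot <- is.list(zernike) && !inherits(zernike, "zernike_spec")
  if (per_spot && length(zernike) != nrow(spots))
    stop("per-spot `zernike` list must have one spec per spot")
  zglob <- if (!per_spot) zernike_surface(zernike, g)

  field <- matrix(0 + 0i, config$slm_pixels, config$slm_pixels)
  for (i in act) {
    ph <- 2 * pi * (config$scale_x * g$u * spots$x[i] +
                    config$scale_y * g$v * spots$y[i] +
                    config$defocus_scale * rho2 * spots$z[i])
    ph <- ph + spots$phase[i]
    ph <- ph + if (per_spot) zernike_surface(zernike[[i]], g) else zglob
    if (spots$L[i] != 0L) ph <- ph + spots$L[i] * g$theta
    field <- field + spots$weight[i] * exp(1i * ph)
  }
  field
}

#' Extract the phase-only hologram from a complex field
#'
#' The hologram displayed on the phase-only SLM is the argument of the total
#' pupil field, wrapped to `[0, 2pi)`. Points of exact destructive
#' interference (zero magnitude) have undefined phase and are assigned 0 —
#' any fixed value is valid since the SLM must display something there.
#'
#' @param field Complex matrix from [superpose_field()].
#' @return Object of class `phase_map`: a matrix of phase values in radians.
#' @export
extract_phase <- function(field) {
  if (all(Mod(field) == 0))
    stop("degenerate field: identically zero, phase undefined")
  ph <- Arg(field) %% (2 * pi)
  ph[Mod(field) == 0] <- 0
  ph[ph >= 2 * pi] <- 0  # guard against rounding at the wrap point
  structure(ph, class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d, range [%.4f, %.4f) rad\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Quantize a phase map to 8-bit SLM levels
#'
#' Level \eqn{k} represents phase \eqn{2\pi k/256}; quantization is
#' round-to-nearest with wrap-around, so the round-trip phase error is at
#' most \eqn{\pi/256}.
#'
#' @param phase A [extract_phase()] phase map (values in `[0, 2pi)`).
#' @return Object of class `quantized_hologram`: integer matrix of levels
#'   0-255.
#' @export
quantize_phase <- function(phase) {
  if (any(phase < 0) || any(phase >= 2 * pi))
    stop("phase values must lie in [0, 2*pi)")
  lev <- round(unclass(phase) * 256 / (2 * pi)) %% 256
  structure(matrix(as.integer(lev), nrow(phase), ncol(phase)),
            class = "quantized_hologram")
}

#' @rdname quantize_phase
#' @param hologram A `quantized_hologram`.
#' @return `dequantize_phase` returns the represented `phase_map`.
#' @export
dequantize_phase <- function(hologram) {
  stopifnot(inherits(hologram, "quantized_hologram"))
  structure(unclass(hologram) * 2 * pi / 256, class = "phase_map")
}

#' @export
print.quantized_hologram <- function(x, ...) {
  cat(sprintf("<quantized_hologram> %d x %d, 8-bit levels %d..%d\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Inverse amplitude weighting against the efficiency envelopes
#'
#' Delivered spot intensity is proportional to \eqn{A_n^2} times the local
#' diffraction efficiency, so multiplying each active spot's amplitude by
#' \eqn{\min(g_{max},\, 1/\sqrt{\eta_{lat}(x,y)\,\eta_{ax}(z)})} flattens the
#' delivered power across the FOV. The gain is capped at `max_gain` to avoid
#' starving on-axis spots for far off-axis ones; weights are then rescaled so
#' the maximum is 1.
#'
#' @param spots A [spot_targets()] table.
#' @param envelope An [envelope_model()].
#' @return The spot table with updated `weight`.
#' @export
compute_amplitude_weights <- function(spots, envelope) {
  stopifnot(inherits(envelope, "envelope_model"))
  validate_spots(spots)
  act <- spots$active
  if (!any(act)) return(spots)
  eff <- lateral_efficiency(spots$x[act], spots$y[act], envelope$dx_max) *
    axial_efficiency(spots$z[act], envelope$axial_sigma)
  gain <- pmin(envelope$max_gain, 1 / sqrt(eff))
  spots$weight[act] <- spots$weight[act] * gain
  wmax <- max(spots$weight[act])
  if (wmax > 0) spots$weight[act] <- spots$weight[act] / wmax
  spots
}

#' Park superfluous foci outside the holographic FOV
#'
#' To keep uncaging power per focus constant while varying the number of
#' stimulation sites, the total focus count is held fixed and superfluous
#' foci are repositioned just outside the holographic FOV: they remain in the
#' hologram (consuming their share of laser power) but fall off the relay
#' optics, so they deliver nothing to the sample.
#'
#' Parked foci are placed at *distinct* positions — a column at
#' `x = park_scale * fov_aperture_halfwidth`, staggered by `park_pitch` in y
#' with a small frozen dither. Coincident parked foci would interfere
#' coherently, making the fraction of power they absorb depend on how many
#' are parked, which defeats the purpose of the protocol (constant power per
#' remaining focus); separated, mutually non-commensurate positions keep
#' each parked focus an independent, equal drain.
#'
#' @param spots A [spot_targets()] table.
#' @param n_active Number of leading spots to keep at their coordinates
#'   (`1 <= n_active <= nrow(spots)`).
#' @param config An [optics_config()] providing the aperture half-width.
#' @param park_scale Multiple of the aperture half-width at which parked
#'   spots sit (> 1 so they fall outside the window).
#' @param park_pitch Spacing of parked foci along y, micrometres.
#' @return The spot table with trailing spots moved to park positions and
#'   flagged `parked`.
#' @export
park_spots <- function(spots, n_active, config, park_scale = 1.2,
                       park_pitch = 6) {
  stopifnot(inherits(config, "optics_config"))
  validate_spots(spots)
  n <- nrow(spots)
  if (length(n_active) != 1L || n_active != round(n_active) ||
      n_active < 1L || n_active > n)
    stop("`n_active` must be an integer in [1, ", n, "]")
  if (park_scale <= 1) stop("`park_scale` must exceed 1")
  if (n_active < n) {
    idx <- (n_active + 1L):n
    m <- length(idx)
    dither <- with_seed(4L, stats::runif(2L * m, -1, 1))
    spots$x[idx] <- park_scale * config$fov_aperture_halfwidth + dither[1:m]
    spots$y[idx] <- park_pitch * (seq_len(m) - (m + 1) / 2) + dither[m + 1:m]
    spots$z[idx] <- 0
    spots$parked[idx] <- TRUE
  }
  spots$parked[seq_len(n_active)] <- FALSE
  spots
}

#' Pad a spot list with parked companion foci
#'
#' Appends placeholder spots and immediately parks them, giving a hologram
#' with `n_total` foci of which only the original spots deliver power — the
#' constant-focus-count convention used throughout characterization.
#'
#' @param spots A [spot_targets()] table.
#' @param n_total Total focus count after padding (>= `nrow(spots)`).
#' @param config An [optics_config()].
#' @inheritParams park_spots
#' @return A [spot_targets()] table with `n_total` rows.
#' @export
add_parked <- function(spots, n_total, config, park_scale = 1.2,
                       park_pitch = 6) {
  n <- nrow(spots)
  if (n_total < n) stop("`n_total` must be at least nrow(spots)")
  if (n_total == n) return(spots)
  pad <- spots[rep(1L, n_total - n), ]
  out <- rbind(as.data.frame(spots), as.data.frame(pad))
  class(out) <- c("spot_targets", "data.frame")
  rownames(out) <- NULL
  park_spots(out, n_active = n, config, park_scale = park_scale,
             park_pitch = park_pitch)
}

#' Generate an 8-bit phase-only hologram for a spot list
#'
#' Full synthesis pipeline: optional inverse amplitude weighting and spot
#' parking, prism-lens-Zernike superposition, phase extraction, and 8-bit
#' quantization. Deterministic: identical inputs give bit-identical
#' holograms.
#'
#' @inheritParams superpose_field
#' @param weighting Apply [compute_amplitude_weights()] first?
#' @param n_active If not `NULL`, [park_spots()] is applied with this count.
#' @param envelope Envelope model for weighting; defaults to
#'   [envelope_from_config()].
#' @param quantize Return the 8-bit `quantized_hologram` (default) or the
#'   continuous `phase_map`.
#' @return A `quantized_hologram` (or `phase_map`), with the final spot table
#'   attached as attribute `"spots"`.
#' @export
#' @examples
#' cfg <- optics_config(slm_pixels = 128)
#' holo <- gen_hologram(spot_targets(x = 5), cfg)
gen_hologram <- function(spots, config, zernike = NULL,
                         weighting = FALSE, n_active = NULL,
                         envelope = NULL, quantize = TRUE) {
  stopifnot(inherits(config, "optics_config"))
  if (!is.null(n_active)) spots <- park_spots(spots, n_active, config)
  if (weighting) {
    if (is.null(envelope)) envelope <- envelope_from_config(config)
    spots <- compute_amplitude_weights(spots, envelope)
  }
  phase <- extract_phase(superpose_field(spots, config, zernike))
  out <- if (quantize) quantize_phase(phase) else phase
  attr(out, "spots") <- spots
  out
}
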