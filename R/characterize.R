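#' Full width at half maximum of a 1D profile
#'
#' Width between the two half-maximum crossings bracketing the profile's
#' peak, located by linear interpolation between samples — the standard
#' resolution metric applied to measured bead/PSF profiles.
#'
#' @param profile Numeric vector of intensities with a unique interior
#'   maximum.
#' @param sample_spacing Distance between samples, micrometres.
#' @return FWHM in micrometres.
#' @export
#' @examples
#' z <- seq(-5, 5, by = 0.05)
#' measure_fwhm(exp(-z^2 / 2), 0.05)   # ~ 2.355 um (Gaussian, sigma = 1)
measure_fwhm <- function(profile, sample_spacing) {
  if (sample_spacing <= 0) stop("`sample_spacing` must be positive")
  n <- length(profile)
  if (n < 3L) stop("profile too short to measure a width")
  ipk <- which.max(profile)
  if (ipk == 1L || ipk == n)
    stop("profile maximum lies on the boundary: FWHM not measurable")
  half <- profile[ipk] / 2

  cross <- function(i0, i1) {
    # linear interpolation of the half-maximum crossing between samples
    i0 + (half - profile[i0]) / (profile[i1] - profile[i0]) * (i1 - i0)
  }
  left <- NA_real_
  for (i in seq(ipk - 1L, 1L)) {
    if (profile[i] <= half) { left <- cross(i, i + 1L); break }
  }
  right <- NA_real_
  for (i in seq(ipk + 1L, n)) {
    if (profile[i] <= half) { right <- cross(i - 1L, i); break }
  }
  if (is.na(left) || is.na(right))
    stop("profile does not cross half-maximum on both sides: FWHM not measurable")
  (right - left) * sample_spacing
}

#' Extract the 1D profile through a volume's global maximum
#'
#' Convenience accessor for PSF characterization: the line through the
#' brightest voxel along one axis.
#'
#' @param volume An [intensity_volume()].
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @return List with `values`, `coords` and `spacing` (micrometres).
#' @export
peak_profile <- function(volume, axis = c("x", "y", "z")) {
  stopifnot(inherits(volume, "intensity_volume"))
  axis <- match.arg(axis)
  idx <- arrayInd(which.max(volume$values), dim(volume$values))
  vals <- switch(axis,
    x = volume$values[idx[1], , idx[3]],
    y = volume$values[, idx[2], idx[3]],
    z = volume$values[idx[1], idx[2], ])
  coords <- switch(axis, x = volume$x, y = volume$y, z = volume$z)
  spacing <- if (length(coords) > 1L) coords[2] - coords[1] else NA_real_
  list(values = vals, coords = coords, spacing = spacing)
}

# Lateral FWHM of the ideal two-photon PSF (|2 J1(t)/t|^4 profile) for a
# uniformly filled circular pupil; closed-form up to the numeric root.
airy_two_photon_fwhm <- function(wavelength, numerical_aperture) {
  airy_amp <- function(t) ifelse(t == 0, 1, 2 * besselJ(t, 1) / t)
  t_half <- stats::uniroot(function(t) airy_amp(t)^4 - 0.5,
                           c(1e-6, 3.8))$root
  t_half * wavelength / (pi * numerical_aperture)
}

#' Integrated signal per stimulation spot
#'
#' Sums the volume's signal (intensity or two-photon, as supplied) over all
#' voxels within `radius` of each spot's nominal position — the simulated
#' analogue of reading out bead fluorescence at an uncaging site.
#'
#' @param volume An [intensity_volume()].
#' @param spots A [spot_targets()] table.
#' @param radius Integration radius in micrometres; default is 3x the
#'   ideal two-photon lateral FWHM for the volume's optics configuration.
#' @return Data frame (one row per spot) with columns `x`, `y`, `z`,
#'   `parked`, `power`.
#' @export
per_spot_power <- function(volume, spots, radius = NULL) {
  stopifnot(inherits(volume, "intensity_volume"))
  validate_spots(spots)
  if (is.null(radius)) {
    cfg <- attr(volume, "config")
    radius <- if (!is.null(cfg))
      3 * airy_two_photon_fwhm(cfg$wavelength, cfg$numerical_aperture)
    else 3 * max(volume$voxel_size, na.rm = TRUE)
  }
  if (radius <= 0) stop("`radius` must be positive")

  rx <- range(volume$x); ry <- range(volume$y); rz <- range(volume$z)
  out <- data.frame(x = spots$x, y = spots$y, z = spots$z,
                    parked = spots$parked, power = NA_real_)
  for (i in seq_len(nrow(spots))) {
    if (spots$x[i] < rx[1] - radius || spots$x[i] > rx[2] + radius ||
        spots$y[i] < ry[1] - radius || spots$y[i] > ry[2] + radius ||
        spots$z[i] < rz[1] - radius || spots$z[i] > rz[2] + radius)
      stop(sprintf("spot %d at (%.1f, %.1f, %.1f) um lies outside the volume",
                   i, spots$x[i], spots$y[i], spots$z[i]))
    jx <- which(abs(volume$x - spots$x[i]) <= radius)
    jy <- which(abs(volume$y - spots$y[i]) <= radius)
    jz <- which(abs(volume$z - spots$z[i]) <= radius)
    if (!length(jx) || !length(jy) || !length(jz)) { out$power[i] <- 0; next }
    d2 <- outer(
      outer((volume$y[jy] - spots$y[i])^2, (volume$x[jx] - spots$x[i])^2, `+`),
      (volume$z[jz] - spots$z[i])^2, `+`)
    sub <- volume$values[jy, jx, jz, drop = FALSE]
    out$power[i] <- sum(sub[d2 <= radius^2])
  }
  out
}

#' Fit a power law to signal versus spot count
#'
#' With total laser power fixed, splitting it over N equal foci leaves each
#' focus with intensity 1/N, and the two-photon signal per focus follows the
#' predicted 1/N^2. Ordinary least squares on log F versus log N; the
#' exponent is reported as a positive magnitude.
#'
#' @param n_values Spot counts (>= 3 values, all positive).
#' @param f_values Per-spot signal at each count (positive).
#' @return List with `exponent` (slope magnitude), `r` (log-log correlation
#'   coefficient, `NA` for constant data) and `fit` (the underlying `lm`).
#' @export
#' @examples
#' fit_power_law(1:10, 1 / (1:10)^2)$exponent   # 2
fit_power_law <- function(n_values, f_values) {
  if (length(n_values) != length(f_values) || length(n_values) < 3L)
    stop("need at least 3 (N, F) pairs")
  if (any(n_values <= 0) || any(f_values <= 0))
    stop("power-law fitting requires strictly positive N and F")
  ln <- log(n_values); lf <- log(f_values)
  fit <- stats::lm(lf ~ ln)
  r <- if (stats::sd(lf) == 0) NA_real_ else stats::cor(ln, lf)
  list(exponent = abs(unname(stats::coef(fit)[2])), r = r, fit = fit)
}

#' Power error from fluorescence error
#'
#' The projector quantifies uncaging power at a site through the quadratic
#' two-photon relation between fluorescence and excitation intensity; the
#' error in power is computed as \eqn{\delta P = 0.5\,\delta F / P}, exactly
#' as used in the characterization. That expression mixes an absolute
#' fluorescence error with a power in the denominator; the physically
#' standard propagated form \eqn{\delta P / P = 0.5\,\delta F / F} is
#' available via `relative = TRUE`.
#'
#' @param delta_f Fluorescence error \eqn{\delta F}.
#' @param power Delivered power P (> 0).
#' @param relative Use the relative-error form (requires `fluorescence`).
#' @param fluorescence Fluorescence F, needed only when `relative = TRUE`.
#' @return \eqn{\delta P} (or \eqn{\delta P / P} when `relative = TRUE`).
#' @export
power_error <- function(delta_f, power, relative = FALSE,
                        fluorescence = NULL) {
  if (any(power <= 0)) stop("`power` must be positive")
  if (relative) {
    if (is.null(fluorescence) || any(fluorescence <= 0))
      stop("`relative = TRUE` requires positive `fluorescence`")
    return(0.5 * delta_f / fluorescence)
  }
  0.5 * delta_f / power
}

#' Fit the empirical Gaussian axial-efficiency envelope
#'
#' Least-squares fit of \eqn{\exp(-z^2/(2\sigma_z^2))} to normalized
#' delivered power versus axial displacement — the empirical fit used for
#' axial amplitude weighting.
#'
#' @param z_values Axial displacements, micrometres (>= 3 points).
#' @param powers Normalized powers in (0, 1].
#' @return Fitted `sigma_z` in micrometres.
#' @export
fit_axial_envelope <- function(z_values, powers) {
  if (length(z_values) != length(powers) || length(z_values) < 3L)
    stop("need at least 3 (z, power) points")
  if (any(powers <= 0) || any(powers > 1 + 1e-9))
    stop("powers must lie in (0, 1] (normalize to the maximum first)")
  # log-linear start: log p = -z^2 / (2 sigma^2)
  slope <- unname(stats::coef(stats::lm(log(powers) ~ I(z_values^2)))[2])
  if (!is.finite(slope) || slope >= 0)
    stop("non-decaying data: axial Gaussian fit failed")
  start <- sqrt(-1 / (2 * slope))
  # 1D least squares refined by bounded search (robust to exact data, where
  # derivative-based optimizers stall on a zero-residual floor)
  rss <- function(sigma) sum((powers - exp(-z_values^2 / (2 * sigma^2)))^2)
  stats::optimize(rss, interval = c(start / 10, start * 10))$minimum
}

#' Least-squares similarity transform between point sets
#'
#' Procrustes/Umeyama fit of `target ~ scale * R %*% measured + translation`
#' minimizing the RMS residual. Used for spot calibration: imaging a single
#' fluorescent bead with a two-foci beam yields mirror-image bead pairs, and
#' the x, y (and z) scaling and rotation factors of the hologram are adjusted
#' by registering measured spot positions to their targets — mirror images
#' are why a reflection component may be admitted.
#'
#' @param measured,target Numeric matrices (n points x d dimensions, d = 2
#'   or 3) in corresponding order; >= 2 points in 2D, >= 3 non-collinear in
#'   3D.
#' @param allow_reflection Admit an orientation-reversing component when it
#'   lowers the residual.
#' @return Object of class `similarity_transform`: list with `scale`,
#'   `rotation_matrix`, `rotation` (angle in radians, 2D only),
#'   `translation`, `reflection` (logical) and `residual` (RMS).
#' @export
#' @examples
#' pts <- cbind(c(0, 1, 0), c(0, 0, 1))
#' fit_similarity_transform(pts, 2 * pts)$scale   # 2
fit_similarity_transform <- function(measured, target,
                                     allow_reflection = FALSE) {
  measured <- as.matrix(measured); target <- as.matrix(target)
  if (!all(dim(measured) == dim(target)))
    stop("`measured` and `target` must have matching dimensions")
  d <- ncol(measured); n <- nrow(measured)
  if (!d %in% c(2L, 3L)) stop("points must be 2D or 3D")
  if (n < d) stop(sprintf("need at least %d point pairs in %dD", d, d))

  mu_x <- colMeans(measured); mu_y <- colMeans(target)
  xc <- sweep(measured, 2, mu_x); yc <- sweep(target, 2, mu_y)
  var_x <- sum(xc^2) / n
  if (var_x < .Machine$double.eps)
    stop("degenerate configuration: measured points coincide")
  sigma <- crossprod(yc, xc) / n               # d x d covariance
  sv <- svd(sigma)
  rank_def <- sum(sv$d > max(sv$d) * 1e-10) < d - 1L
  if (rank_def || (d == 3L && sum(sv$d > max(sv$d) * 1e-10) < 2L))
    stop("degenerate configuration: points are collinear/coplanar beyond recovery")

  s <- rep(1, d)
  det_uv <- det(sv$u %*% t(sv$v))
  if (!allow_reflection && det_uv < 0) s[d] <- -1
  if (allow_reflection && det_uv < 0) {
    # Umeyama: with reflection admitted, the unconstrained optimum keeps
    # det < 0 exactly when that lowers the residual
    s <- rep(1, d)
  }
  rot <- sv$u %*% diag(s, d) %*% t(sv$v)
  scale <- sum(sv$d * s) / var_x
  if (scale <= 0) stop("degenerate configuration: non-positive fitted scale")
  trans <- mu_y - scale * as.vector(rot %*% mu_x)
  fitted <- sweep(scale * measured %*% t(rot), 2, trans, `+`)
  residual <- sqrt(mean(rowSums((target - fitted)^2)))

  structure(list(
    scale = scale,
    rotation_matrix = rot,
    rotation = if (d == 2L) atan2(rot[2, 1], rot[1, 1]) else NA_real_,
    translation = trans,
    reflection = det(rot) < 0,
    residual = residual
  ), class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat("<similarity_transform>\n")
  cat(sprintf("  scale       %.6g\n", x$scale))
  if (!is.na(x$rotation))
    cat(sprintf("  rotation    %.6g rad (%.2f deg)\n",
                x$rotation, x$rotation * 180 / pi))
  cat(sprintf("  translation (%s) um\n",
              paste(format(x$translation, digits = 6), collapse = ", ")))
  cat(sprintf("  reflection  %s, RMS residual %.3g um\n",
              x$reflection, x$residual))
  invisible(x)
}
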