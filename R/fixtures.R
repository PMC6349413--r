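# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators are pure functions of their inputs
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic fluorescent-bead phantom
#'
#' Description of a bead preparation standing in for the two-photon bead
#' stacks used to characterize the projector: 1 um beads for fluorescence /
#' power readout, 100 nm (sub-resolution) beads for PSF measurement.
#'
#' @param positions Matrix (n x 3) of bead centres in micrometres, or a
#'   length-3 vector for a single bead.
#' @param diameter Bead diameter in micrometres (default 1).
#' @param background Constant background level added everywhere.
#' @param noise One of `"none"`, `"gaussian"` (read noise, standard
#'   deviation `noise_sigma` relative to the noise-free peak) or
#'   `"poisson"` (shot noise after scaling by `poisson_scale`).
#' @param noise_sigma Gaussian noise level as a fraction of peak.
#' @param poisson_scale Expected counts at the noise-free peak.
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `bead_phantom`.
#' @export
bead_phantom <- function(positions, diameter = 1.0, background = 0,
                         noise = c("none", "gaussian", "poisson"),
                         noise_sigma = 0.01, poisson_scale = 1000,
                         seed = 1L) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("`positions` must be n x 3 (x, y, z in um)")
  if (diameter <= 0) stop("`diameter` must be positive")
  noise <- match.arg(noise)
  structure(list(positions = positions, diameter = diameter,
                 background = background, noise = noise,
                 noise_sigma = noise_sigma, poisson_scale = poisson_scale,
                 seed = as.integer(seed)),
            class = "bead_phantom")
}

#' Render a bead phantom into an image volume
#'
#' Beads are rendered incoherently: a sphere of the phantom's diameter is
#' rasterized at each position (total deposit proportional to bead volume,
#' so summed signal is linear in bead count), convolved with the supplied
#' PSF by FFT, then background and seeded noise are added. Sub-voxel beads
#' deposit their full signal at the nearest voxel, so a 100 nm bead imaged on
#' a ~0.2 um grid reports the PSF itself.
#'
#' @param phantom A [bead_phantom()].
#' @param psf An [intensity_volume()] holding the (two-photon) PSF; it is
#'   normalized to unit sum internally and defines the output grid.
#' @return An [intensity_volume()] on the PSF's grid.
#' @export
make_bead_volume <- function(phantom, psf) {
  stopifnot(inherits(phantom, "bead_phantom"),
            inherits(psf, "intensity_volume"))
  dims <- dim(psf$values)
  vol <- array(0, dims)
  r <- phantom$diameter / 2
  for (i in seq_len(nrow(phantom$positions))) {
    p <- phantom$positions[i, ]
    if (p[1] < min(psf$x) || p[1] > max(psf$x) ||
        p[2] < min(psf$y) || p[2] > max(psf$y) ||
        p[3] < min(psf$z) || p[3] > max(psf$z))
      stop(sprintf("bead %d at (%.2f, %.2f, %.2f) um lies outside the volume",
                   i, p[1], p[2], p[3]))
    jx <- which(abs(psf$x - p[1]) <= r)
    jy <- which(abs(psf$y - p[2]) <= r)
    jz <- which(abs(psf$z - p[3]) <= r)
    deposit <- 4 / 3 * pi * r^3
    filled <- FALSE
    if (length(jx) && length(jy) && length(jz)) {
      d2 <- outer(outer((psf$y[jy] - p[2])^2, (psf$x[jx] - p[1])^2, `+`),
                  (psf$z[jz] - p[3])^2, `+`)
      inside <- array(d2 <= r^2, dim = c(length(jy), length(jx), length(jz)))
      if (any(inside)) {
        add <- array(0, dim(inside))
        add[inside] <- deposit / sum(inside)
        vol[jy, jx, jz] <- array(vol[jy, jx, jz], dim(add)) + add
        filled <- TRUE
      }
    }
    if (!filled) {
      # sub-voxel bead: all signal at the nearest voxel centre
      vol[which.min(abs(psf$y - p[2])), which.min(abs(psf$x - p[1])),
          which.min(abs(psf$z - p[3]))] <-
        vol[which.min(abs(psf$y - p[2])), which.min(abs(psf$x - p[1])),
            which.min(abs(psf$z - p[3]))] + deposit
    }
  }

  kernel <- psf$values / sum(psf$values)
  if (nrow(phantom$positions) > 0L && any(vol > 0)) {
    # cyclic FFT convolution with the PSF centred at its own peak
    pk <- arrayInd(which.max(kernel), dims)
    kshift <- kernel
    for (ax in 1:3) {
      ord <- (seq_len(dims[ax]) + pk[ax] - 2L) %% dims[ax] + 1L
      kshift <- switch(ax, kshift[ord, , , drop = FALSE],
                       kshift[, ord, , drop = FALSE],
                       kshift[, , ord, drop = FALSE])
    }
    vol <- Re(stats::fft(stats::fft(vol) * stats::fft(kshift),
                         inverse = TRUE)) / prod(dims)
    vol[vol < 0] <- 0  # clip FFT rounding residue
  }
  vol <- vol + phantom$background

  peak <- max(vol)
  if (phantom$noise == "gaussian" && peak > 0) {
    noise <- with_seed(phantom$seed,
                       stats::rnorm(length(vol), 0,
                                    phantom$noise_sigma * peak))
    vol <- pmax(vol + array(noise, dim(vol)), 0)
  } else if (phantom$noise == "poisson" && peak > 0) {
    lam <- vol / peak * phantom$poisson_scale
    counts <- with_seed(phantom$seed, stats::rpois(length(vol), lam))
    vol <- array(counts, dim(vol)) / phantom$poisson_scale * peak
  }
  intensity_volume(vol, x = psf$x, y = psf$y, z = psf$z)
}

#' Deterministic well-separated spot grid
#'
#' Lays `n` spots on a centred square grid at the requested pitch, filled in
#' row-major serpentine order, for scaling and parking experiments. Errors
#' when the grid cannot fit inside the requested extent.
#'
#' With `dither > 0` the lattice pitch is inflated to `spacing * (1 + 2 *
#' dither)` and each spot receives a frozen pseudo-random offset of up to
#' `dither * spacing` per axis, so the minimum pairwise spacing is still
#' guaranteed while the positions become non-commensurate. Exactly periodic
#' layouts are the worst case for the direct superposition algorithm:
#' intermodulation orders of the phase-only hologram then land exactly on
#' other foci, so characterization experiments that read out per-spot power
#' use a dithered layout.
#'
#' @param n Number of spots (>= 1).
#' @param spacing Minimum pairwise spacing, micrometres.
#' @param extent Side length of the square region the spots must fit in,
#'   micrometres.
#' @param dither Fractional position dither (0 = exact lattice).
#' @return A [spot_targets()] table (z = 0).
#' @export
#' @examples
#' make_spot_grid(10, spacing = 5, extent = 30)
make_spot_grid <- function(n, spacing, extent, dither = 0) {
  if (n < 1L || n != round(n)) stop("`n` must be a positive integer")
  if (spacing <= 0 || extent <= 0)
    stop("`spacing` and `extent` must be positive")
  if (dither < 0 || dither >= 0.5) stop("`dither` must lie in [0, 0.5)")
  if (n == 1L) return(spot_targets(x = 0, y = 0, z = 0))
  side <- ceiling(sqrt(n))
  jit <- dither * spacing
  pitch <- spacing + 2 * jit
  if ((side - 1) * pitch + 2 * jit > extent)
    stop(sprintf(
      "cannot place %d spots with %.3g um spacing inside a %.3g um extent",
      n, spacing, extent))
  ax <- (seq_len(side) - 1 - (side - 1) / 2) * pitch
  xs <- numeric(n); ys <- numeric(n)
  k <- 0L
  for (row in seq_len(side)) {
    cols <- if (row %% 2L == 1L) seq_len(side) else rev(seq_len(side))
    for (col in cols) {
      k <- k + 1L
      if (k > n) break
      xs[k] <- ax[col]; ys[k] <- ax[row]
    }
    if (k >= n) break
  }
  if (jit > 0) {
    d <- with_seed(3L, stats::runif(2L * n, -jit, jit))
    xs <- xs + d[1:n]; ys <- ys + d[n + 1:n]
  }
  spot_targets(x = xs, y = ys, z = 0)
}

#' Displacement-scan line of spots across the holographic FOV
#'
#' `n` spots along x spanning exactly `[-halfspan, halfspan]`, used to map
#' the lateral diffraction-efficiency envelope and to demonstrate inverse
#' amplitude weighting. Interior spots are dithered slightly off the even
#' grid and every spot receives a distinct transverse (y) offset, both from
#' a frozen pseudo-random stream: commensurate positions or shared rows
#' would let intermodulation and conjugate orders of the phase-only
#' superposition coincide with measurement foci and corrupt per-spot power
#' readout.
#'
#' @param n Number of spots (>= 2).
#' @param halfspan Half-extent of the scan along x, micrometres; the
#'   endpoints sit exactly at `-halfspan` and `+halfspan`.
#' @param x_dither Maximum interior dither as a fraction of `halfspan`.
#' @param y_spread Half-range of the transverse offsets, micrometres.
#' @return A [spot_targets()] table (z = 0).
#' @export
#' @examples
#' make_line_targets(5, halfspan = 90)
make_line_targets <- function(n, halfspan, x_dither = 0.05, y_spread = 8) {
  if (n < 2L || n != round(n)) stop("`n` must be an integer >= 2")
  if (halfspan <= 0) stop("`halfspan` must be positive")
  x <- seq(-halfspan, halfspan, length.out = n)
  d <- with_seed(5L, c(stats::runif(n - 2, -x_dither, x_dither) * halfspan,
                       stats::runif(n, -y_spread, y_spread)))
  if (n > 2L) x[2:(n - 1)] <- x[2:(n - 1)] + d[seq_len(n - 2)]
  spot_targets(x = x, y = d[(n - 1):(2 * n - 2)], z = 0)
}
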