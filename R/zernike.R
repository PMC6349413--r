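#' Normalized pupil coordinate grid
#'
#' Cartesian coordinates \eqn{(u, v)} over the square SLM working area, scaled
#' so the inscribed pupil disk has radius 1. Matrix rows run along \eqn{v}
#' (y, downward image convention), columns along \eqn{u} (x, rightward); the
#' grid contains the exact origin so FFT propagation centres correctly.
#'
#' @param n_pix Grid size (pixels per side).
#' @return List with matrices `u`, `v`, `rho`, `theta` and logical `mask`
#'   (`rho <= 1`, the pupil disk).
#' @export
pupil_grid <- function(n_pix) {
  n_pix <- as.integer(n_pix)
  if (is.na(n_pix) || n_pix < 2L) stop("`n_pix` must be an integer >= 2")
  ax <- (seq_len(n_pix) - 1 - n_pix %/% 2) * (2 / n_pix)
  u <- matrix(ax, n_pix, n_pix, byrow = TRUE)
  v <- matrix(ax, n_pix, n_pix)
  rho <- sqrt(u^2 + v^2)
  list(u = u, v = v, rho = rho, theta = atan2(v, u), mask = rho <= 1)
}

# Radial Zernike polynomial R_p^{|q|}(rho), standard factorial series.
zernike_radial <- function(p, absq, rho) {
  out <- array(0, dim = dim(rho))
  for (k in 0:((p - absq) / 2)) {
    ck <- (-1)^k * factorial(p - k) /
      (factorial(k) * factorial((p + absq) / 2 - k) *
         factorial((p - absq) / 2 - k))
    out <- out + ck * rho^(p - 2 * k)
  }
  out
}

check_zernike_index <- function(p, q) {
  if (length(p) != 1L || length(q) != 1L ||
      p != round(p) || q != round(q) || p < 0 ||
      abs(q) > p || (p - abs(q)) %% 2 != 0)
    stop(sprintf(
      "invalid Zernike index (p = %s, q = %s): need p >= 0, |q| <= p, p - |q| even",
      format(p), format(q)))
  invisible(TRUE)
}

#' Evaluate one Zernike polynomial on the pupil
#'
#' OSA/ANSI double-index convention: `p` is the radial order, `q` the signed
#' azimuthal order (`q >= 0` gives the cosine term, `q < 0` the sine term),
#' with orthonormal scaling so every polynomial has unit RMS over the unit
#' disk. Points outside the pupil (`rho > 1`) are set to 0.
#'
#' @param p Radial order (non-negative integer).
#' @param q Azimuthal order (integer, `|q| <= p`, `p - |q|` even).
#' @param grid A [pupil_grid()] or an integer grid size.
#' @return Phase surface in radians, `n_pix` x `n_pix` matrix.
#' @export
#' @examples
#' g <- pupil_grid(128)
#' piston <- zernike_eval(0, 0, g)      # 1 on the disk
#' astig  <- zernike_eval(2, -2, g)     # sqrt(6) rho^2 sin(2 theta)
zernike_eval <- function(p, q, grid) {
  if (is.numeric(grid) && length(grid) == 1L) grid <- pupil_grid(grid)
  check_zernike_index(p, q)
  norm <- sqrt(2 * (p + 1) / (1 + (q == 0)))
  ang <- if (q >= 0) cos(q * grid$theta) else sin(-q * grid$theta)
  z <- norm * zernike_radial(p, abs(q), grid$rho) * ang
  z[!grid$mask] <- 0
  z
}

#' Zernike aberration specification
#'
#' A set of Zernike terms \eqn{C_q^p Z_q^p(u, v)} (coefficients in radians of
#' RMS phase) used to encode or correct optical aberrations in the hologram.
#' An empty spec encodes zero aberration.
#'
#' @param p,q Integer vectors of radial and signed azimuthal orders (recycled
#'   to common length with `coeff`).
#' @param coeff Numeric coefficients, radians RMS.
#' @return An object of class `zernike_spec` (a data frame with columns
#'   `p`, `q`, `coeff`).
#' @export
#' @examples
#' zernike_spec(p = 2, q = -2, coeff = 1.5)   # oblique astigmatism
#' zernike_spec()                             # no aberration
zernike_spec <- function(p = integer(), q = integer(), coeff = numeric()) {
  n <- max(length(p), length(q), length(coeff))
  if (n > 0L) {
    p <- rep_len(as.numeric(p), n)
    q <- rep_len(as.numeric(q), n)
    coeff <- rep_len(as.numeric(coeff), n)
    for (i in seq_len(n)) check_zernike_index(p[i], q[i])
    if (any(!is.finite(coeff))) stop("Zernike coefficients must be finite")
  }
  structure(data.frame(p = p, q = q, coeff = coeff),
            class = c("zernike_spec", "data.frame"))
}

#' @export
print.zernike_spec <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<zernike_spec> empty (no aberration)\n")
  } else {
    cat(sprintf("<zernike_spec> %d term(s)\n", nrow(x)))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Aberration surface from a Zernike specification
#'
#' Linear combination \eqn{\sum C_q^p Z_q^p(u,v)} over the spec's terms; the
#' empty spec yields the all-zero surface.
#'
#' @param spec A [zernike_spec()] (or `NULL` for none).
#' @param grid A [pupil_grid()] or integer grid size.
#' @return Phase surface in radians.
#' @export
zernike_surface <- function(spec, grid) {
  if (is.numeric(grid) && length(grid) == 1L) grid <- pupil_grid(grid)
  n_pix <- nrow(grid$u)
  out <- matrix(0, n_pix, n_pix)
  if (is.null(spec) || nrow(spec) == 0L) return(out)
  stopifnot(inherits(spec, "zernike_spec"))
  for (i in seq_len(nrow(spec)))
    out <- out + spec$coeff[i] * zernike_eval(spec$p[i], spec$q[i], grid)
  out
}

#' Convert Noll single indices to OSA/ANSI double indices
#'
#' Interoperability helper: many adaptive-optics tools order Zernike modes by
#' the Noll single index `j` (1 = piston, 2/3 = tilt, 4 = defocus, ...).
#'
#' @param j Vector of Noll indices (integers >= 1).
#' @return Data frame with columns `j`, `p` (radial), `q` (signed azimuthal).
#' @export
#' @examples
#' noll_to_osa(1:6)  # piston, tilts, defocus, astigmatisms
noll_to_osa <- function(j) {
  j <- as.integer(j)
  if (any(is.na(j)) || any(j < 1L)) stop("Noll indices must be integers >= 1")
  jmax <- max(j)
  tab <- matrix(NA_integer_, jmax, 2)
  jj <- 0L
  n <- 0L
  while (jj < jmax) {
    for (am in seq(n %% 2L, n, by = 2L)) {
      if (am == 0L) {
        jj <- jj + 1L
        if (jj <= jmax) tab[jj, ] <- c(n, 0L)
      } else {
        # pair of +/- modes; Noll gives the even j the cosine (q > 0) term
        m1 <- if ((jj + 1L) %% 2L == 0L) am else -am
        if (jj + 1L <= jmax) tab[jj + 1L, ] <- c(n, m1)
        if (jj + 2L <= jmax) tab[jj + 2L, ] <- c(n, -m1)
        jj <- jj + 2L
      }
    }
    n <- n + 1L
  }
  data.frame(j = j, p = tab[j, 1], q = tab[j, 2])
}
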