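test_that("FWHM measurement recovers the Gaussian closed form", {
  sp <- 0.04
  z <- seq(-6, 6, by = sp)
  prof <- exp(-z^2 / 2)  # sigma = 1 um
  expect_equal(measure_fwhm(prof, sp), 2 * sqrt(2 * log(2)), tolerance = 0.01)
  # scale invariance of the half-maximum and linearity in sample spacing
  expect_equal(measure_fwhm(37.3 * prof, sp), measure_fwhm(prof, sp))
  expect_equal(measure_fwhm(prof, 2 * sp), 2 * measure_fwhm(prof, sp))
  # boundary maximum and non-crossing profiles are not measurable
  expect_error(measure_fwhm(exp(seq(0, 1, 0.1)), sp), "boundary")
  expect_error(measure_fwhm(c(0.9, 0.95, 1, 0.95, 0.9), sp),
               "not measurable")
})

test_that("power-law fitting recovers exact and noisy exponents", {
  n <- 1:10
  fit <- fit_power_law(n, 1 / n^2)
  expect_equal(fit$exponent, 2, tolerance = 1e-12)
  expect_equal(abs(fit$r), 1, tolerance = 1e-12)
  const <- fit_power_law(n, rep(3.7, 10))
  expect_equal(const$exponent, 0)
  expect_true(is.na(const$r))
  # multiplicative log-normal noise, sigma = 0.05
  withr::with_seed(11, {
    f_noisy <- 1 / n^2 * exp(rnorm(10, 0, 0.05))
  })
  expect_gt(fit_power_law(n, f_noisy)$exponent, 1.9)
  expect_lt(fit_power_law(n, f_noisy)$exponent, 2.1)
  expect_error(fit_power_law(1:2, 1:2), "at least 3")
  expect_error(fit_power_law(n, c(-1, 2:10)), "positive")
})

test_that("power error follows the printed formula and its relative variant", {
  expect_equal(power_error(0, 2), 0)
  expect_equal(power_error(0.2, 1.0), 0.1)
  # halving P doubles dP at fixed dF
  expect_equal(power_error(0.2, 0.5), 2 * power_error(0.2, 1.0))
  expect_error(power_error(0.1, 0), "positive")
  expect_equal(power_error(0.2, 1, relative = TRUE, fluorescence = 4), 0.025)
  expect_error(power_error(0.1, 1, relative = TRUE), "fluorescence")
})

test_that("axial Gaussian envelope fitting recovers the generating width", {
  z <- seq(-12, 12, by = 1.5)
  p <- exp(-z^2 / 50)  # sigma = 5
  expect_equal(fit_axial_envelope(z, p), 5, tolerance = 0.01)
  # z-scaling doubles sigma
  expect_equal(fit_axial_envelope(2 * z, p), 10, tolerance = 0.01)
  withr::with_seed(3, {
    noisy <- pmin(pmax(p + rnorm(length(z), 0, 0.02), 1e-6), 1)
  })
  expect_equal(fit_axial_envelope(z, noisy), 5, tolerance = 0.05)
  expect_error(fit_axial_envelope(z, rep(0.8, length(z))), "non-decaying")
  expect_error(fit_axial_envelope(z, p * 2), "normalize")
})

test_that("similarity-transform fitting is exact on noiseless correspondences", {
  pts <- cbind(c(0, 3, 1, -2, 4), c(0, 1, 4, 2, -1))
  # identity
  id <- fit_similarity_transform(pts, pts)
  expect_equal(id$scale, 1, tolerance = 1e-12)
  expect_equal(id$rotation, 0, tolerance = 1e-12)
  expect_lt(id$residual, 1e-12)
  # known rotation + scale + translation recovered to 1e-6
  th <- 30 * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  target <- sweep(1.2 * pts %*% t(rot), 2, c(5, -2), `+`)
  fit <- fit_similarity_transform(pts, target)
  expect_equal(fit$scale, 1.2, tolerance = 1e-6)
  expect_equal(fit$rotation, th, tolerance = 1e-6)
  expect_equal(unname(fit$translation), c(5, -2), tolerance = 1e-6)
  expect_false(fit$reflection)
  expect_lt(fit$residual, 1e-9)
})

test_that("bead mirror images are recovered only when reflection is allowed", {
  pts <- cbind(c(0, 3, 1, -2), c(0, 1, 4, 2))
  mirrored <- cbind(-pts[, 1], pts[, 2])
  with_ref <- fit_similarity_transform(pts, mirrored, allow_reflection = TRUE)
  expect_true(with_ref$reflection)
  expect_lt(with_ref$residual, 1e-12)
  no_ref <- fit_similarity_transform(pts, mirrored, allow_reflection = FALSE)
  expect_false(no_ref$reflection)
  expect_gt(no_ref$residual, 0.1)
})

test_that("3D similarity fits work and degenerate configurations error", {
  pts3 <- cbind(c(0, 1, 0, 2, -1), c(0, 0, 1, 1, 2), c(0, 1, 2, -1, 0))
  th <- 0.4
  rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  target <- sweep(0.8 * pts3 %*% t(rz), 2, c(1, 2, 3), `+`)
  fit <- fit_similarity_transform(pts3, target)
  expect_equal(fit$scale, 0.8, tolerance = 1e-6)
  expect_equal(fit$rotation_matrix, rz, tolerance = 1e-6)
  coincident <- matrix(1, 4, 2)
  expect_error(fit_similarity_transform(coincident, coincident),
               "degenerate")
  collinear <- cbind(1:4, 1:4, 1:4)
  expect_error(fit_similarity_transform(collinear, collinear), "degenerate")
  expect_error(fit_similarity_transform(pts3[1:2, ], pts3[1:2, ]),
               "at least 3")
})

test_that("per-spot power integrates the focal signal", {
  cfg <- small_config(128, pad = 4)
  # single centred focus: per-spot power captures nearly all 2P signal
  spots1 <- spot_targets(0)
  vol1 <- two_photon_volume(propagate(gen_hologram(spots1, cfg), cfg, 0))
  p1 <- per_spot_power(vol1, spots1)
  expect_equal(p1$power, sum(vol1$values), tolerance = 0.05)
  # two well-separated equal spots at mirrored efficiency: equal powers
  spots2 <- spot_targets(x = c(-6.2, 6.2), y = c(2.7, -2.7))
  vol2 <- two_photon_volume(propagate(gen_hologram(spots2, cfg), cfg, 0))
  p2 <- per_spot_power(vol2, spots2)$power
  expect_equal(p2[1] / p2[2], 1, tolerance = 0.1)
  expect_error(per_spot_power(vol2, spot_targets(400)), "outside")
})
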