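test_that("the transform step conserves energy (Parseval)", {
  cfg <- small_config(128, pad = 2)
  spots <- spot_targets(x = c(-6, 2, 9), y = c(3, -1, 5))
  vol <- propagate(gen_hologram(spots, cfg, quantize = FALSE), cfg, 0,
                   envelope = FALSE)
  pupil_energy <- sum(pupil_grid(128)$mask)  # unit-amplitude disk
  expect_equal(sum(vol$values), pupil_energy, tolerance = 1e-6)
})

test_that("a flat hologram focuses on-axis, prisms and lenses steer it", {
  cfg <- small_config(128, pad = 4)
  # flat phase: diffraction-limited focus at the origin
  v0 <- propagate(gen_hologram(spot_targets(0, phase = 0), cfg), cfg, 0)
  pk <- arrayInd(which.max(v0$values), dim(v0$values))
  expect_equal(v0$x[pk[2]], 0)
  expect_equal(v0$y[pk[1]], 0)
  # off-peak intensity at 3x the FWHM radius is < 5% of the peak
  prof <- peak_profile(v0, "x")
  fwhm <- measure_fwhm(prof$values, prof$spacing)
  far <- abs(v0$x) >= 3 * fwhm
  expect_lt(max(v0$values[, far, 1]), 0.05 * max(v0$values))

  # prism hologram: peak lands at the target within one voxel
  target <- c(5, -3)
  v1 <- propagate(gen_hologram(spot_targets(target[1], target[2]), cfg),
                  cfg, 0)
  pk1 <- arrayInd(which.max(v1$values), dim(v1$values))
  expect_lt(abs(v1$x[pk1[2]] - target[1]), v1$voxel_size["dx"] + 1e-12)
  expect_lt(abs(v1$y[pk1[1]] - target[2]), v1$voxel_size["dy"] + 1e-12)

  # lens hologram for z = +5: brighter in the z = 5 plane than at 0
  v2 <- propagate(gen_hologram(spot_targets(0, z = 5), cfg), cfg, c(0, 5))
  expect_gt(max(v2$values[, , 2]), max(v2$values[, , 1]))
})

test_that("adding a ramp to the hologram translates the volume", {
  cfg <- small_config(128, pad = 4)
  spots <- spot_targets(x = c(-4, 3), y = c(2, -5))
  v1 <- propagate(gen_hologram(spots, cfg), cfg, 0)
  shifted <- spots
  shifted$x <- shifted$x + 6
  v2 <- propagate(gen_hologram(shifted, cfg), cfg, 0)
  p1 <- per_spot_power(v1, spots)
  p2 <- per_spot_power(v2, shifted)
  # same foci, same delivered power pattern up to the efficiency envelope
  eff1 <- lateral_efficiency(spots$x, spots$y, 24)
  eff2 <- lateral_efficiency(shifted$x, shifted$y, 24)
  expect_equal(p2$power / p1$power, eff2 / eff1, tolerance = 0.02)
})

test_that("the aperture window zeroes intensity outside and only outside", {
  cfg <- optics_config(slm_pixels = 128, pad_factor = 2,
                       fov_aperture_halfwidth = 10)
  spots <- spot_targets(x = c(0, 18), y = c(4, 0))
  vol <- propagate(gen_hologram(spots, cfg), cfg, 0)
  clipped <- apply_aperture(vol, cfg)
  inside_pk <- per_spot_power(clipped, spots[1, ])$power
  expect_equal(inside_pk, per_spot_power(vol, spots[1, ])$power)
  expect_equal(per_spot_power(clipped, spots[2, ])$power, 0)
  outside <- abs(vol$x) > 10
  expect_true(all(clipped$values[, outside, ] == 0))
  # infinite half-width is the identity
  expect_equal(apply_aperture(vol, halfwidth = Inf)$values, vol$values)
})

test_that("two-photon signal is the square of intensity", {
  vol <- intensity_volume(array(c(0, 1, 2, 3), c(2, 2, 1)),
                          x = c(0, 1), y = c(0, 1), z = 0)
  tp <- two_photon_volume(vol)
  expect_equal(tp$values, vol$values^2)
  # doubling intensity quadruples the signal everywhere
  vol2 <- vol; vol2$values <- 2 * vol$values
  expect_equal(two_photon_volume(vol2)$values, 4 * tp$values)
  # zero maps to zero and metadata is preserved
  expect_equal(tp$x, vol$x)
  z0 <- intensity_volume(array(0, c(2, 2, 1)), c(0, 1), c(0, 1), 0)
  expect_equal(two_photon_volume(z0)$values, z0$values)
})

test_that("a vortex charge yields an annular focus with a dark core", {
  cfg <- small_config(128, pad = 4)
  vol <- propagate(gen_hologram(spot_targets(0, L = 1), cfg), cfg, 0)
  ring_max <- max(vol$values)
  core <- vol$values[which.min(abs(vol$y)), which.min(abs(vol$x)), 1]
  expect_lt(core, 0.01 * ring_max)
})

test_that("propagate validates its inputs", {
  cfg <- small_config(64)
  holo <- gen_hologram(spot_targets(0), cfg)
  expect_error(propagate(holo, cfg, numeric(0)), "z_planes")
  cfg2 <- small_config(128)
  expect_error(propagate(holo, cfg2, 0), "slm_pixels")
})

test_that("intensity volumes round-trip through multi-page TIFF", {
  cfg <- small_config(64, pad = 2)
  vol <- propagate(gen_hologram(spot_targets(c(-3, 4)), cfg), cfg,
                   c(-2, 0, 2))
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume_tiff(vol, path)
  back <- read_volume_tiff(path)
  expect_equal(back$values, vol$values, tolerance = 1e-6)
  expect_equal(back$x, vol$x)
  expect_equal(back$z, vol$z)
})
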