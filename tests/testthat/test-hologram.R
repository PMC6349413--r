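test_that("single-spot fields are pure prism/lens phases", {
  cfg <- small_config(64)
  g <- pupil_grid(64)
  # centred spot with zero offset: constant field, flat phase
  f0 <- superpose_field(spot_targets(0, 0, 0, phase = 0), cfg)
  expect_equal(Arg(f0), matrix(0, 64, 64))
  # lateral spot: linear ramp along u with slope 2*pi*alpha*x
  x1 <- 3
  f1 <- superpose_field(spot_targets(x1, 0, 0, phase = 0), cfg)
  expected <- exp(2i * pi * cfg$scale_x * g$u * x1)
  expect_equal(f1, expected, tolerance = 1e-12)
})

test_that("two equal opposed spots give a binary {0, pi} hologram", {
  cfg <- small_config(64)
  spots <- spot_targets(x = c(-4, 4), phase = 0)
  ph <- extract_phase(superpose_field(spots, cfg))
  d <- pmin(abs(ph - 0), abs(ph - pi), abs(ph - 2 * pi))
  expect_lt(max(d), 1e-9)
})

test_that("superposition is the sum of single-spot fields", {
  cfg <- small_config(64)
  spots <- spot_targets(x = c(-5, 2, 7), y = c(1, -3, 4), z = c(0, 2, -1),
                        weight = c(1, 0.7, 0.4), phase = c(0.3, 1.2, 2.9))
  joint <- superpose_field(spots, cfg)
  parts <- lapply(1:3, function(i) superpose_field(spots[i, ], cfg))
  expect_equal(joint, parts[[1]] + parts[[2]] + parts[[3]], tolerance = 1e-12)
  # inactive spots contribute nothing
  spots$active[2] <- FALSE
  expect_equal(superpose_field(spots, cfg), parts[[1]] + parts[[3]],
               tolerance = 1e-12)
})

test_that("phase extraction wraps to [0, 2pi) and flags degenerate fields", {
  f <- matrix(exp(1i * 1.7), 8, 8)
  expect_equal(unclass(extract_phase(f)), matrix(1.7, 8, 8))
  expect_equal(unclass(extract_phase(matrix(-1 + 0i, 4, 4))),
               matrix(pi, 4, 4))
  # conjugation maps phase to (2pi - phase) mod 2pi
  f2 <- matrix(exp(1i * c(0.4, 2.8, 4.1, 6.0)), 2, 2)
  expect_equal((unclass(extract_phase(f2)) +
                  unclass(extract_phase(Conj(f2)))) %% (2 * pi),
               matrix(0, 2, 2), tolerance = 1e-12)
  # zero-magnitude points get phase 0; an all-zero field errors
  f3 <- matrix(c(0 + 0i, 1i, -1i, 1 + 0i), 2, 2)
  expect_equal(unclass(extract_phase(f3))[1, 1], 0)
  expect_error(extract_phase(matrix(0 + 0i, 4, 4)), "degenerate")
})

test_that("conjugate-spot symmetry negates the phase map", {
  cfg <- small_config(64)
  a <- spot_targets(x = c(3, -2), y = c(1, 5), z = c(2, -1), phase = 0)
  b <- spot_targets(x = -c(3, -2), y = -c(1, 5), z = -c(2, -1), phase = 0)
  pa <- extract_phase(superpose_field(a, cfg))
  pb <- extract_phase(superpose_field(b, cfg))
  expect_lt(max(phase_dist(pa, (2 * pi - pb) %% (2 * pi))), 1e-9)
})

test_that("8-bit quantization round-trips within pi/256", {
  ph <- structure(matrix(seq(0, 2 * pi - 1e-9, length.out = 10^2), 10, 10),
                  class = "phase_map")
  q <- quantize_phase(ph)
  expect_true(all(q >= 0 & q <= 255))
  expect_lt(max(phase_dist(ph, dequantize_phase(q))), pi / 256 + 1e-12)
  # anchor levels: 0 -> 0, pi -> 128, wrap just below 2*pi -> 0
  anchors <- structure(matrix(c(0, pi, 2 * pi * 255.6 / 256, 0.01), 2, 2),
                       class = "phase_map")
  expect_equal(as.vector(unclass(quantize_phase(anchors))),
               c(0L, 128L, 0L, 0L))
  expect_error(quantize_phase(structure(matrix(7, 2, 2),
                                        class = "phase_map")), "2\\*pi")
})

test_that("inverse amplitude weighting flattens ideal delivered intensity", {
  env <- envelope_model(dx_max = 112.5, axial_sigma = 50, max_gain = 4)
  spots <- spot_targets(x = c(0, 112.5, 60), y = 0, z = c(0, 0, 30))
  w <- compute_amplitude_weights(spots, env)
  # origin spot has gain 1 before renormalization -> smallest weight after
  gains <- w$weight / w$weight[1]
  expect_equal(gains[2], 1 / sqrt((2 / pi)^2), tolerance = 1e-9)
  eff <- lateral_efficiency(spots$x, spots$y, env$dx_max) *
    axial_efficiency(spots$z, env$axial_sigma)
  expect_equal(cv(w$weight^2 * eff), 0, tolerance = 1e-12)
  expect_equal(max(w$weight), 1)
  # far spot with efficiency below 1/g_max^2 is capped at g_max
  far <- spot_targets(x = c(0, 220), y = 0)
  wf <- compute_amplitude_weights(far, envelope_model(112.5, 50, max_gain = 4))
  expect_equal(wf$weight[2] / wf$weight[1], 4)
})

test_that("parking moves trailing spots outside the aperture window", {
  cfg <- optics_config()
  spots <- make_spot_grid(4, 5, 30)
  same <- park_spots(spots, 4, cfg)
  expect_equal(same$x, spots$x)
  expect_false(any(same$parked))
  parked <- park_spots(spots, 1, cfg)
  expect_equal(sum(parked$parked), 3)
  expect_true(all(abs(parked$x[2:4]) > cfg$fov_aperture_halfwidth))
  # parked foci sit at distinct positions (no coherent pile-up)
  expect_gt(min(dist(cbind(parked$x[2:4], parked$y[2:4]))), 2)
  expect_error(park_spots(spots, 0, cfg), "n_active")
  expect_error(park_spots(spots, 5, cfg), "n_active")
})

test_that("a parked-out spot still consumes its equal share of power", {
  cfg <- small_config(300, pad = 2)
  spots <- make_spot_grid(4, 5, 30, dither = 0.15)
  # 1 active of 4: delivered power at the active spot should match the
  # 4-way equal split, not the single-spot value
  p_of <- function(sp) {
    vol <- apply_aperture(propagate(gen_hologram(sp, cfg), cfg, 0), cfg)
    per_spot_power(vol, sp[1, ])$power
  }
  p_parked <- p_of(park_spots(spots, 1, cfg))
  p_full <- p_of(spots)
  p_alone <- p_of(spots[1, ])
  expect_equal(p_parked / p_full, 1, tolerance = 0.15)
  expect_lt(p_parked / p_alone, 0.5)
})

test_that("gen_hologram is deterministic and obeys the ramp-shift identity", {
  cfg <- small_config(64)
  spots <- spot_targets(x = c(-3, 1, 6), y = c(2, -4, 0))
  h1 <- gen_hologram(spots, cfg)
  h2 <- gen_hologram(spots, cfg)
  expect_identical(unclass(h1), unclass(h2))
  # single centred spot gives a flat (single-level) hologram
  flat <- gen_hologram(spot_targets(0, phase = 0), cfg)
  expect_equal(length(unique(as.vector(unclass(flat)))), 1L)
  # shifting all spots adds a linear pupil ramp (mod 2pi)
  dx <- 2.5
  g <- pupil_grid(64)
  ph1 <- gen_hologram(spots, cfg, quantize = FALSE)
  shifted <- spots
  shifted$x <- shifted$x + dx
  ph2 <- gen_hologram(shifted, cfg, quantize = FALSE)
  ramp <- (2 * pi * cfg$scale_x * g$u * dx) %% (2 * pi)
  expect_lt(max(phase_dist(ph2, (unclass(ph1) + ramp) %% (2 * pi))), 1e-9)
})

test_that("add_parked pads to the requested focus count", {
  cfg <- optics_config()
  line <- make_line_targets(5, 90)
  padded <- add_parked(line, 10, cfg)
  expect_equal(nrow(padded), 10L)
  expect_equal(padded$x[1:5], line$x)
  expect_equal(sum(padded$parked), 5L)
  expect_true(all(abs(padded$x[6:10]) > cfg$fov_aperture_halfwidth))
  expect_identical(add_parked(line, 5, cfg), line)
  expect_error(add_parked(line, 3, cfg), "n_total")
})
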