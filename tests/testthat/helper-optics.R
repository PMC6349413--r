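# small, fast configurations used across tests; physics (NA, wavelength)
# matches the full-size system so closed-form oracles carry over
small_config <- function(n_pix = 128L, pad = 4L) {
  optics_config(slm_pixels = n_pix, pad_factor = pad)
}

cv <- function(x) stats::sd(x) / mean(x)

# circular distance between phase maps (radians)
phase_dist <- function(a, b) {
  d <- (unclass(a) - unclass(b)) %% (2 * pi)
  pmin(d, 2 * pi - d)
}
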