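Package: holoproj
Title: Hologram Synthesis and Fourier-Optics Simulation for Multi-Site
    Two-Photon Photostimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a spatial-light-modulator (SLM) holographic
    projector for multi-site two-photon glutamate uncaging. Synthesizes 3D
    multi-focus phase-only holograms by prism-lens-Zernike superposition,
    models the SLM diffraction-efficiency envelopes (lateral sinc-squared,
    empirical axial Gaussian) with inverse amplitude weighting, simulates the
    resulting two-photon focal volume by scalar Fourier optics, and implements
    the quantitative characterization and calibration procedures (FWHM,
    per-spot power, 1/N^2 scaling, spot parking, Zernike aberration
    correction, bead mirror-image similarity-transform calibration), so the
    optical behaviour of the hologram engine can be checked in simulation
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
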