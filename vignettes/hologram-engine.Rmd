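---
title: "The hologram engine: model, calibration and simulated characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hologram engine: model, calibration and simulated characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The optical model

holoproj simulates the computational core of an SLM-based holographic
projector for multi-site two-photon (2P) glutamate uncaging. A phase-only
spatial light modulator in a plane conjugate to the objective's back focal
plane displays a hologram; its far field at the focal region is a set of
diffraction-limited foci that act as simultaneous uncaging sites on
dendritic spines.

The hologram is synthesized by the direct prism–lens superposition
algorithm. With normalized pupil coordinates $(u, v)$ (pupil-edge radius 1),
the complex input field is

$$\psi(u, v) = \sum_{n=1}^{N} A_n \exp\Big( 2\pi i \big[ \alpha u x_n +
\beta v y_n + \gamma (u^2 + v^2) z_n \big] + i \sum_{p,q} C_q^p Z_q^p(u, v)
+ i L_n \theta \Big),$$

and the SLM displays $\arg\{\psi\}$ quantized to 8 bits. The linear
(prism) term steers focus $n$ laterally to $(x_n, y_n)$, the quadratic
(lens) term axially to $z_n$, the Zernike sum pre-compensates optical
aberrations, and the azimuthal term $L\theta$ encodes a Laguerre–Gaussian
vortex used to centre the SLM on the optical axis (an $L \ge 1$ focus is a
ring with a dark core, a sensitive alignment target). With the normalized
pupil convention the physical scaling factors are $\alpha = \beta =
\mathrm{NA}/\lambda$ and $\gamma = -\mathrm{NA}^2/(2 n_i \lambda)$
($n_i$ the immersion index); they are stored mutable in `optics_config()`
because in practice they absorb calibration adjustments. Note the lens term
acts on *pupil* coordinates — a quadratic in image coordinates would be a
per-spot constant and could not refocus light.

Three hardware limits shape delivered power:

* **Space–bandwidth FOV.** First-order foci can only be steered within
  $\pm dx_{max}$, $dx_{max} = \lambda N_{pix} / (4\,\mathrm{NA})$
  (`fov_half_range()`); 225 µm full side for the default 600-pixel working
  area at 750 nm, NA 1.0.
* **Pixelation envelope.** The finite SLM pixel footprint imposes a
  separable $\mathrm{sinc}^2(\pi x / 2 dx_{max})\,
  \mathrm{sinc}^2(\pi y / 2 dx_{max})$ efficiency decline
  (`lateral_efficiency()`; unnormalized $\mathrm{sinc}(t) = \sin t / t$ —
  stated explicitly to avoid the $\pi$-scaling dialect trap). At the
  Nyquist displacement the efficiency is exactly $(2/\pi)^2$. Axially, an
  empirical Gaussian $\exp(-z^2/2\sigma_z^2)$ models the measured decline;
  $\sigma_z$ defaults to 50 µm, keeping efficiency above 50% over ±35 µm,
  and is a fitted, configurable parameter, not a physical claim.
* **Relay aperture.** The relay optics between SLM and scanning mirrors
  clip beams beyond a much smaller window (~70×70 µm² with a 20×
  objective, ~30×30 µm² with 60×). Since the actual relay geometry is not
  modelled, this is a hard square transmission window of half-width
  `fov_aperture_halfwidth` (35 µm default for the 20× profile, 15 µm for
  60×) applied in the image plane. Its operational role — parked spots
  receive zero power — is reproduced; its soft physical edge is not.

## Propagation engine

`propagate()` is a scalar Fourier-optics oracle: the unit-amplitude pupil
field $e^{i\phi}$ is apodized by the pupil disk, multiplied per z-plane by
the paraxial defocus factor $\exp(-2\pi i \gamma (u^2+v^2) z)$ (the
conjugate of the hologram's lens phase, so a focus programmed at $z_1$ is
sharpest in the plane $z = z_1$), zero-padded by `pad_factor` and
Fourier-transformed; intensity is the squared modulus and the 2P signal its
square. The transform is unitary (Parseval to machine precision), the image
covers exactly the holographic FOV $[-dx_{max}, dx_{max})$, and sampling is
$2 dx_{max} / (\mathrm{pad}\cdot N_{pix})$ — 0.1875 µm for the default
600-pixel, pad-2 configuration, fine enough that per-spot power integration
is stable. The pixel-footprint envelope is applied analytically in the
image plane, equivalent by the array theorem to unit-fill-factor pixels;
this keeps FFTs at `pad_factor * N_pix` instead of super-sampling the SLM.
One physical consequence of simulating the pixelated device with a DFT:
orders diffracted beyond $\pm dx_{max}$ re-enter as grating replicas on the
opposite side (attenuated by the envelope at their landing position),
exactly as a pixelated SLM behaves.

Defocus uses the same paraxial $\gamma$ as the hologram synthesis rather
than a high-NA Debye integral: self-consistent, cheap, and sufficient for
the *relative* claims tested. Absolute PSF widths are therefore treated
only as lower bounds on hardware: the ideal 2P lateral FWHM is ~0.28 µm
against the measured 0.49 µm (60×), and the ideal axial FWHM ~1.3 µm
against the measured 2.7 µm.

## Per-spot phase offsets

The free phase of each complex amplitude $A_n$ matters. If every spot
carries the same initial phase, the inter-spot interference of the
phase-only hologram piles into structured intermodulation ("ghost")
orders; on a regular spot lattice those orders land exactly on other foci
and per-spot powers become wildly non-uniform. `spot_targets()` therefore
assigns each spot a fixed pseudo-random offset by list position (the
standard random-superposition refinement of the prism–lens algorithm),
frozen so `gen_hologram()` remains a pure deterministic function of its
inputs. Explicit `phase = 0` recovers the textbook special cases (two
opposed equal spots give a binary $\{0, \pi\}$ hologram, coordinate
negation conjugates the field).

Two further consequences of phase-only extraction are deliberately left
uncorrected, matching the direct algorithm:

* discarded amplitude structure appears as inter-spot cross-talk; per-spot
  powers fluctuate by several percent even with good layouts, and
  iterative optimizers (Gerchberg–Saxton and variants) that would fix this
  are intentionally absent;
* the power allocated to a spot is proportional to its squared weight only
  while no component dominates the pupil-plane interference — with very
  few foci the allocation becomes strongly super-linear in weight (for two
  foci the delivered ratio at weight ratio 0.6 is ≈0.12, not 0.36; the
  package's FFT result matches the closed-form integral for this case to
  four decimals). Characterization protocols therefore keep the total
  focus count high and constant, as below.

## Characterization protocols

These mirror the bench characterization of the projector, and their
defaults are the package's study conditions.

**1/N² scaling.** With total input power fixed, each of $N$ equal foci
receives ~$1/N$ of the intensity, so the 2P signal per focus follows
$1/N^2$. The experiment generates holograms for $N = 1 \dots 10$ spots on
a 5 µm serpentine grid within ±15 µm, propagates at the focal plane,
squares, integrates per-spot signal and fits a log–log line
(`fit_power_law()`); the ideal-simulation exponent is ≈2.05 (hardware gave
1.8). Power error uses the printed hybrid formula $\delta P = 0.5 \delta F
/ P$ exactly as stated — dimensionally odd (an absolute fluorescence error
over a power) but kept for fidelity, with the standard propagated form
$\delta P / P = 0.5\,\delta F / F$ behind `relative = TRUE`.

**Spot parking.** To vary the number of *stimulation* sites without
changing power per site, the focus count is held fixed and superfluous
foci are parked just outside the aperture window, where they consume their
share of laser power but deliver none. `park_spots()` places parked foci
at *distinct* staggered positions (a y-pitched column at
$1.2\times$ the aperture half-width, with a frozen sub-µm dither) rather
than one coincident point: coincident parked foci would interfere
coherently and the power they absorb would depend on how many are parked,
defeating the protocol. With distinct positions the simulated active-spot
power is constant to within a few percent across 1–10 active of 10 total.

**Envelope flattening.** Delivered power is flattened by multiplying each
spot's amplitude by $\min(g_{max}, 1/\sqrt{\eta_{lat}\,\eta_{ax}})$
(`compute_amplitude_weights()`; gain capped at 4 so far-off-axis spots
cannot starve the rest, weights renormalized to maximum 1 — whether to
renormalize is not externally constrained; max-1 is chosen and
documented). The demonstration measures a 5-spot line spanning
±0.8 $dx_{max}$ inside a 10-focus hologram (5 parked companions — the
constant-focus-count protocol again, which also keeps the allocation in
its near-linear regime). Layouts avoid commensurate positions: interior
line spots are dithered off the even grid and every spot has a distinct
transverse offset (`make_line_targets()`), because on harmonic layouts
intermodulation and conjugate orders coincide with measurement foci.
Weighted per-spot 2P power lands at CV ≈ 4% versus ≈ 46% unweighted.

**Aberration correction.** Aberrations are expressed in Zernike
polynomials on the normalized pupil, OSA/ANSI double indices with
orthonormal (unit-RMS) scaling — the convention is stated because
coefficient magnitudes do not transfer between conventions, and published
per-system coefficient values are therefore not used as test values; a
Noll single-index converter is provided for interoperability. Injecting an
astigmatism surface into the propagation (a "system" aberration) and
encoding its negation in the hologram restores ≥99% of the unaberrated 2P
peak. Depth-dependent corrections are supported by per-spot coefficient
sets; the default is one global set.

**Geometric calibration.** Aligning hologram coordinates to microscope
coordinates uses bead images: a two-foci beam imaged on a single
fluorescent bead yields mirror-image bead pairs, and the x, y, z scaling
and rotation factors are adjusted by registering measured positions to
targets. `fit_similarity_transform()` implements the least-squares
(Procrustes/Umeyama) similarity fit; reflections are admitted only on
request, precisely because mirror images are expected in this calibration.

**FWHM.** `measure_fwhm()` interpolates the two half-maximum crossings
linearly; profiles whose maximum touches the boundary, or that never cross
half-maximum, are rejected rather than extrapolated.

## Synthetic data

`bead_phantom()` / `make_bead_volume()` emulate the 2P bead stacks used on
the bench: 1 µm beads for power readout, 100 nm (sub-resolution) beads for
PSF measurement. Beads are rendered incoherently — a rasterized sphere
(total deposit proportional to bead volume, so summed signal is linear in
bead count) convolved with the supplied PSF by cyclic FFT — plus constant
background and seeded Gaussian read noise (default 1% of peak) or Poisson
shot noise. Generators are pure functions of their parameters and seed.
What this does *not* emulate: coherent imaging, scattering and
depth-dependent aberrations in tissue, photobleaching, detector nonlinearity
and drift. Tests passing on these phantoms validate the computational
pipeline, not performance in brain slices.

## Numerical choices and problem sizes

* Pupil grid: square `slm_pixels` working area with the inscribed disk as
  the pupil; the grid contains the exact origin so the DFT centres
  correctly. Zero-magnitude field points (destructive-interference nodes)
  take phase 0 — any fixed value is valid, the SLM must display something.
* Quantization: round-to-nearest into 256 levels with wrap-around;
  round-trip error ≤ π/256 by construction.
* Test and characterization sizes: module tests use 64–300 px pupils;
  end-to-end characterizations run the full 600 px, pad-2 configuration
  (1200² FFTs). PSF widths are measured at 128 px with pad 16 laterally
  (0.023 µm sampling) and pad 4 axially (0.05 µm z-steps), since the ideal
  PSF depends only on NA and wavelength, not on pixel count.
* The axial Gaussian envelope fit uses a log-linear start refined by a
  bounded 1D least-squares search, robust on exact (zero-residual) data.
* The printed "220 × 220 µm²" system FOV corresponds to the formula value
  225 µm at λ = 750 nm, 600 px, NA 1.0; the difference is treated as
  author rounding.

## Known limitations

* Scalar, paraxial propagation: no vectorial high-NA effects, so absolute
  PSF widths are idealized bounds.
* The relay aperture is a hard square window; the true soft, possibly
  circular fall-off is not modelled.
* The axial efficiency Gaussian is an empirical hardware effect applied as
  a per-spot weighting model, not emergent from propagation.
* Direct superposition only: per-spot power uniformity is limited by
  phase-only cross-talk; layouts with commensurate spacings remain
  adversarial.
* No photochemistry or biology: uncaging yield, EPSPs and synaptic
  integration are outside the engine's scope.
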