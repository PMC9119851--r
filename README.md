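# fourpi

Dynamic spline PSF modeling and single-molecule localization analysis
for 4Pi interferometric microscopy (4Pi-STORM), in R with a compiled
fitting core.

## The problem

In 4Pi detection, fluorescence collected through two opposed objective
lenses self-interferes and is recorded as four channels (p1, s1, p2, s2)
at relative interference phases of 0°/90°/180°/270°. The PSF is
modulated along z with period `p = λ₀ / (2 n_s) ≈ 253 nm` (~λ/2), which
makes each single-fluorophore image a sensitive reporter of the
emitter's z coordinate — but only modulo the fringe period, and only if
the model used for fitting matches the instrument's current
interference phase. Phase drift of the optical cavity biases z and, past
~60° of mismatch, produces periodic "ghost image" artifacts in which
localizations are displaced by multiples of the fringe spacing.

`fourpi` is for analysts of 4Pi-SMLM data (and developers of such
analyses) who need the full chain:

* **PSF calibration** — a four-channel bead z-scan is cropped,
  downsampled and smoothed, then encoded as a multichannel 3D cubic
  spline,
  `h(x, y, z, c | x₀, y₀, z₀, A, b) = b + A·f_S(x−x₀, y−y₀, z−z₀, c)`,
  with 64 polynomial coefficients per volume cell (`calibrate_psf`,
  `compute_spline_coefficients`).
* **Dynamic phase** — the model is split into an envelope and an
  interference modulation (Fourier low-pass along z, 500 nm cutoff) plus
  the modulation's Hilbert quadrature, so a model at any phase is
  `h_env + cosΔφ·h_mod + sinΔφ·h_mod⁹⁰` (`dynamic_spline_psf`,
  `psf_at_phase`). The experimental phase is measured from the data by
  fitting emitter images with 12 phase-shifted models and locating the
  minimum of the mean-Chi-square-versus-phase curve (`estimate_phase`,
  `phase_trace`), then converted to a z correction through a calibrated
  slope of ≈ −p/2π ≈ −40 nm/rad (`calibrate_phase_to_z`,
  `correct_phase_drift`).
* **Localization** — detection on the interference-free channel sum,
  grouping of multi-frame switching events, multi-start
  Levenberg–Marquardt fits of 7×7×4 ROIs against the spline with z
  starts spaced finer than the fringe period, Poisson-weighted
  Chi-square objective, and Cramér–Rao lower bounds from the Poisson
  Fisher information of the same model (`detect_candidates`,
  `group_events`, `fit_localization`, `compute_crlb`,
  `artifact_fraction`).
* **Corrections** — quadratic channel registration with cubic
  convolution warping, redundant all-pairs cross-correlation drift
  correction, wavelength/refractive-index z rescaling, multistep z-stage
  scan merging with per-step phases, and ratiometric two-color
  assignment with fluorophore-specific (s/p-rescaled) PSF models.
* **Simulator** — a scalar interference model of the symmetric 4Pi PSF
  (quadrature channel phases, defocus-spread lateral Gaussian, Gaussian
  coherence envelope, Poisson noise, phase/sample drift) that generates
  bead scans, emitter images and movies with ground truth, so every
  stage above is testable without a microscope.

## Worked example

Calibrate a PSF from a (simulated) bead scan, measure the experimental
phase from 250 emitter images recorded after the cavity drifted, and fit
them with the phase-matched model:

```r
library(fourpi)
cfg <- fourpi_config()    # 680 nm, n_s 1.346, 138.2 nm pixels, ...

scan <- simulate_bead_scan(cfg, z_range = 3000, n_steps = 1500, n_xy = 17)
psf  <- dynamic_spline_psf(preprocess_bead_scan(scan, downsample = 5))
#> spline_psf: 19595264 coefficients (16 x 16 x 299 cells, 4 channels)

cfg_exp <- cfg; cfg_exp$phase <- 0.35   # the drifted instrument
set.seed(1)
images <- lapply(1:250, function(i) simulate_emitter_image(
  cfg_exp, ground_truth_emitter(x = runif(1, -60, 60),
                                y = runif(1, -60, 60),
                                z = runif(1, -100, 100),
                                photons = 8000, background = 10)))

est <- estimate_phase(images, psf, z_start_range = c(-250, 250))
#> experimental phase: 0.366 +- 0.027 rad

fits <- fit_localization(images, psf_at_phase(psf, est$phase))
calibrate_phase_to_z(psf)$slope
#> phase-to-z slope: -39.5 nm/rad
compute_crlb(psf_at_phase(psf, est$phase),
             c(0, 0, 0, 8000 / psf_flux(psf$template, 0), 10))
#> CRLB at focus: x 1.36  y 1.36  z 0.71 nm
```

The estimated phase (0.366 ± 0.027 rad) recovers the injected drift of
0.35 rad within its quoted precision; all 250 fits converge, the median
photon estimate is 7,971 against the true 8,000, and the bound says
sub-1.5 nm lateral / sub-1 nm axial precision is available at this
photon budget — which the fits attain (see the test suite's
CRLB-efficiency checks). The spline model carries the 4 × 64 × 16 × 16 ×
299 ≈ 1.96 × 10⁷ coefficients of the standard 17 × 17 × 300 voxel
calibration.

## Documentation

The methods vignette (`vignettes/dynamic-spline-psf.Rmd`) describes the
model and its assumptions, the phase-shifting and phase-estimation
algorithms, the fitting objective and its relation to the CRLB, what the
simulator does and does not emulate, and the package's numerical and
design choices.
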