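---
title: "A size/disparity-correlated cross-correlation model of spatial stereoresolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A size/disparity-correlated cross-correlation model of spatial stereoresolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stereocorr)
```

## The scientific problem

Random-dot stereograms can depict a surface corrugated in depth: the
binocular disparity of the dots varies sinusoidally (or as a square wave)
with vertical position, `d(y) = A sin(2πfy + φ)` with amplitude `A`
(arcmin) and corrugation frequency `f` (cycles/deg). Humans stop resolving
such corrugations above roughly 3–4 cpd, far below their acuity for
luminance patterns. Correlation-based models explain this: V1-like
detectors report the normalized cross-correlation of the two eyes' images
inside a receptive-field-sized window, and a window of SD ~3 arcmin
(the smallest useful size given the eye's optics) reproduces the human
limit for sine-wave corrugations. The classical model breaks down for
square waves — being piecewise flat, they remain detectable at arbitrarily
high amplitude in the model, but not in people. `stereocorr` implements
the repaired encoding stage: detectors tuned to larger disparities use
larger windows (a size/disparity correlation), which makes square waves
and sine waves equally detectable and restores the 1/f upper depth limit
for both.

## Pipeline and parameters

The model is a four-stage pipeline, one package module per stage:

1. **Stimulus synthesis** (`generate_dot_field()`, `render_stereogram()`).
   Dots are placed uniformly (Poisson count, mean `density × area`),
   with ±1 contrast polarities in equal proportion on a mean-gray (0)
   background. Disparity is applied symmetrically, ±d/2 per eye; the
   encoding stage is indifferent to how the total offset is split, and the
   symmetric split keeps the cyclopean image centred. Matched
   disparity-noise stimuli draw each dot's disparity independently from
   the parent grating's marginal distribution (±A for a square parent, the
   arcsine law on [−A, A] for a sine parent), so grating and noise span
   the same disparity range — the discrimination must rest on the spatial
   *arrangement* of disparity, not its range. Defaults: density 120
   dots/deg², dot diameter 1.2 arcmin, field 2° × 2° (at least two periods
   at the lowest core frequency). These dot statistics are not specified
   by the modelling study itself (they live in the cited psychophysics);
   the defaults are representative of dense-RDS psychophysics and are
   configurable.
2. **Optics** (`blur_and_scale()`): isotropic Gaussian PSF of SD 2 arcmin
   (truncated at 4 SD, < 1e−4 mass lost), identical in both eyes, then
   area-true block averaging to the 0.6 arcmin/px working grid.
   Rendering happens at 0.15 arcmin/px so that amplitudes down to 0.3
   arcmin (half a working pixel) survive into the blurred image.
3. **Correlator population** (`correlation_surface()`): for each vertical
   position (every working row) and each preferred disparity on the grid,
   the Pearson correlation of the window-weighted pixel sets, the left
   window fixed at one x-column, the right offset by the preferred
   disparity. Window: 2-D Gaussian of SD `σ(Δx)`, cut off at two standard
   deviations. Size/disparity relations: constant `σ = 3`; quadratic
   `σ = 3 + 0.032 Δx²`; linear `σ = 3 + 0.24|Δx|`. The linear slope is a
   package default chosen to agree with the quadratic relation at
   Δx = 7.6 arcmin (the published value of the linear coefficient is not
   legible in the available text) and is exposed as a parameter.
4. **Decision** (`build_bank()`, `decide_interval()`): the observer knows
   the blocked frequency but not amplitude, phase or waveform. Templates
   are the mean correlation surface over `n` independent stereograms per
   condition (full profile: 36 phases × 6 amplitudes × 2 waveforms = 432
   grating templates, plus 12 noise templates, `n = 100`). Each interval
   is scored by its best Pearson match across grating and across noise
   templates, and the interval with the larger `M_grating − M_noise` is
   chosen. The per-condition SD surface is computed and stored but does
   not enter the match (the match statistic uses means only); a
   variance-weighted variant is a natural extension hook. A
   frequency-agnostic observer (`decide_interval_unknown_frequency()`)
   maximizes the grating match across a list of banks.

## Numerical and design choices

- **Disparity grid.** "−13 to 13 arcmin in steps of 0.6" is not realizable
  on a 0.6-arcmin pixel grid (26/0.6 is not an integer); the package uses
  the on-grid version −12.6..+12.6, 43 detectors. Preferred disparities
  must be whole working pixels, since the right window is displaced by
  whole pixels.
- **Window truncation.** The cut-off `|offset| < 2σ` is strict; at exact
  multiples (2σ = 10 px for σ = 3) the boundary pixel is excluded. σ
  enters the Gaussian smoothly and is quantized only through this
  truncation.
- **Edge policy.** Detectors whose window (left or right) does not fit in
  the raster are flagged undefined rather than computed with a shrunken
  window — shrinking would silently change the size/disparity relation
  near the raster edges. Undefined entries are excluded from templates and
  from the match consistently. Windows with numerically zero variance
  (blank image regions) are likewise flagged, never reported as ±1.
- **Within-window disparity range** (`disparity_range_in_window()`) uses
  the 1-SD contour as the window extent (`halfwidth = σ`); this is the
  convention under which the five analytic anchor values (0.8, 2.4, 14,
  4.8 and 10.7 arcmin at 3.8 cpd) all follow from the closed forms
  `A(1−cos 2πfh)` (peak-centred) and `2A sin 2πfh` (zero-crossing-centred).
  The range is computed by exact enumeration of interval extrema, not by
  sampling.
- **Fast stimulus path.** Rendering at 0.15 arcmin/px, blurring, and block
  averaging compose into a single linear kernel: the dot disc convolved
  with the PSF and the working-pixel aperture (the box apertures are
  folded into the Gaussian as `pitch²/12` per axis, < 0.4% of the SD).
  The default `stimulus_method = "kernel"` splats this composite radial
  kernel directly on the working grid; `"raster"` runs the explicit
  pipeline. Away from the raster border the two agree to ~0.3% RMS (the
  raster path loses dots displaced outside the raster; the kernel path
  omits the luminance clipping of overlapping same-polarity dots, which
  touches well under 1% of pixels at the default density). Templates and
  trials always use a single path, so the observer's priors match its
  inputs exactly.
- **Seeds.** All Monte-Carlo stages derive per-sample seeds from a master
  seed through a fixed 32-bit congruential schedule (`derive_seed()`);
  banks, experiments and the acceptance script are bit-reproducible from
  one integer.
- **Square-wave ties.** `sgn(0) = +1`: a window centred exactly on an edge
  assigns the edge row to the rising half-cycle.
- **Confidence intervals** are Wilson score intervals (the method is not
  stated in the source analyses; Wilson has good small-n coverage and
  never escapes [0, 100]).
- **Upper depth limit**: the largest amplitude whose percent correct
  exceeds the criterion (default 80%), refined by interpolation in
  log-amplitude between the bracketing amplitudes — the target
  relationship is a power law, so interpolation is done on the log scale.
  Conditions that never fall below the criterion are censored (the
  classical model's square waves have no upper limit at all); the log-log
  slope is fit by least squares over uncensored frequencies.

## The energy-model equivalence

A windowed cross-correlator is not a neuron; the package therefore checks
numerically that it equals a population of standard binocular energy
units. Each unit is a quadrature pair of Gabor subunits with position
disparity `Δx`, zero phase disparity, and a shared envelope; its response
decomposes exactly as `S = B + L + R` into a binocular cross term and two
monocular energies (`energy_unit_response()`). Summing `B`, `L`, `R` over
a bank of spatial frequencies (log-spaced, trapezoid weights with the
polar area element) and orientations (uniform) and normalizing as
`C_int = B_int / (2√(L_int·R_int))` reproduces the windowed correlation
(`integrated_correlation()`). Numerical choices:

- The Gabor envelopes use the same 2σ box truncation as the correlation
  window, so the bank integral lands on exactly the correlator's support.
- The radial integral is truncated at 16 cpd: the 2-arcmin PSF leaves less
  than 1e−3 of amplitude beyond it. The quadrature is convergence-checked
  by doubling the bank density (the run aborts if the value moves by more
  than `tol = 1e-3`) rather than trusting a fixed density.
- The factor 2 carried by the cross term `B` (forced by `S = B + L + R`)
  is divided out in the normalization, so identical windowed patches give
  exactly +1 and anti-correlated ones −1.
- The zero-spatial-frequency unit is excluded from the bank by default.
  Its subunits simply sum the windowed pixel values, so its `B`, `L`, `R`
  are exactly the mean-luminance terms of the analytic derivation;
  no cortical cell is DC-tuned, and with the unit removed the bank sum
  equals the covariance-normalized (Pearson) correlation — the quantity
  the correlator module computes — to quadrature accuracy (max deviation
  ~0.005 over 50 random windows). With `dc_unit = "include"` the bank
  instead converges to the uncentered correlation; the difference is the
  windowed mean-luminance term, which is *not* negligible for σ ≈ 3 arcmin
  windows (they hold only ~5–20 independent blurred patches, at any dot
  density), although it vanishes in the large-window limit the analytic
  derivation contemplates.

## What the simulations do and do not show

The synthetic stimuli emulate dense random-dot psychophysics: uniform dot
placement, equal bright/dark polarity, additive luminance with clipping,
a single Gaussian PSF, and disparity applied as pure horizontal offsets.
They do not emulate monitor gamma, fixation jitter, vergence noise,
vertical disparities, occlusion geometry, or neuronal noise — the model
is deterministic given the stimulus, so all trial-to-trial variability is
stimulus-driven. Percent-correct levels therefore bound what the
*encoding* supports; human observers additionally face internal noise.
Model accuracies at the lowest amplitude (0.3 arcmin, half a detector
step) depend strongly on the decision stage's ability to exploit
sub-step structure and are not calibrated to human stereoacuity.

## Problem sizes used in the shipped checks

The full study profile (36 phases, 100 stereograms per template,
frequencies to 0.1 cpd, detectors to ±140 arcmin) is available through
the same functions but is not what the shipped tests run. The package's
own verification uses reduced Monte-Carlo profiles, chosen once:

- Headline condition (3.8 cpd, 7.6 arcmin, quadratic relation): 12
  phases, 50 stereograms per template, 150 trials per waveform, 1°×2°
  fields ~ the reduced profile reproduces the ~80%-correct level for both
  waveforms with a ±8-point band.
- Depth-limit power law (linear relation, sine): frequencies 0.5, 1 and
  2 cpd with per-frequency amplitude ladders (geometric, ratio 1.5)
  centred on the disparity-gradient expectation ~30/f arcmin, detector
  grids extended to ±120/±54/±36 arcmin respectively, 12 phases, 12
  stereograms per template, 40 trials per amplitude. Wider grids at lower
  frequencies mirror the study design (performance at low f stays perfect
  to tens of arcmin). The ladder centring follows the classical 1/f
  depth-limit law from the psychophysical literature; the measured limits
  and slope remain entirely data-driven, and censoring is reported rather
  than extrapolated.
- Energy equivalence: 50 random windows of a 1.3 cpd, 5.1 arcmin sine
  stereogram, mixed preferred disparities (hence mixed window sizes).
- Exchangeability control: amplitude 0, 400 trials against a deliberately
  small bank — with no signal the two intervals are statistically
  identical whatever the priors, so accuracy must sit at 50%.

## Known limitations

- Only horizontal corrugations; vertical-grating anisotropy is out of
  scope.
- One window size per preferred disparity (the smallest useful), not a
  population of sizes.
- The frequency integration in the energy bank is unweighted; evidence
  that large disparities are carried by low luminance frequencies would
  argue for down-weighting high frequencies at large Δx.
- No neuronal noise, so absolute sensitivities (especially at 0.3 arcmin)
  are upper bounds.
- The correlator evaluates one x-column of left-window positions;
  multiple columns are configurable but quadratically more expensive.
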