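---
title: "Phase-variance OCT angiography processing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-variance OCT angiography processing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvocta)
```

## The problem

OCT angiography (OCTA) maps retinal and choroidal blood flow without dye
injection by detecting temporal fluctuation of the complex OCT signal at
voxels containing moving blood cells. Doing this over a wide field of view is
a race against the eye: a raster of repeated B-scans dense enough to resolve
capillaries takes seconds even at megahertz A-scan rates, during which the
eye drifts axially (corrupting phase) and saccades laterally (corrupting
whole B-scans). `pvocta` implements the complete processing chain for a
swept-source phase-variance OCTA system — spectral reconstruction, flow
contrast, motion correction, and depth-resolved *en face* visualization —
together with a scan-protocol planner and a physics-based interferogram
simulator that makes the chain testable without instrument hardware.

## Scan-protocol arithmetic

A raster OCTA protocol is defined by the field of view, the scan step, the
number of B-scan repeats per slow-scanner position (N = 5 for the megahertz
FDML protocols modeled here), the spectral samples per A-scan, and the sweep
rate. `plan_acquisition()` derives A-scan and position counts by truncating
extent/step toward zero: 9 mm at 7 µm steps gives 1285 A-scans per B-scan
(1285.7 rounded *up* would not match the printed count). Instrument tables
often use hardware round numbers instead (1024 A-scans over a nominal 5 mm at
5 µm steps), so protocols accept explicit count overrides and the
`protocol_preset()` values carry the published counts verbatim.

Reported values follow instrument-table conventions: decimal gigabytes
(10^9 bytes — 5120 × 1024 × 1024 × 2 B rounds to 11 GB, where binary GiB
would not), minutes to one decimal, seconds to the nearest integer.
Acquisition time uses the B-scan repetition period (which includes scanner
fly-back) when the protocol states one, otherwise the zero-fly-back
derivation `a_scans / sweep_rate`; both modes are exposed because published
time estimates mix the two. The spatial sampling ratio `step / spot` with the
half-spot undersampling criterion (`step > beam/2`) quantifies whether a
protocol can resolve structures at the optical resolution limit.

One printed inconsistency is preserved deliberately: the commercial 6 × 6 mm
preset's repetition time (5 ms) is slightly below its A-scan time at the
stated sweep rate, so the planner's lower-bound invariant is only asserted
for the self-consistent columns.

## The forward model (simulator)

`simulate_volume()` generates raw spectral fringes from a layered scattering
phantom under a scalar, single-scattering model. Each A-scan fringe is

```
F(k_m) = S(k_m) [ DC + sum_j 2 sqrt(r_j) cos(2 n k_m z_j + theta(k_m)) ] + FP(m) + noise
```

with `S` the source envelope (Gaussian, 1065 nm center, 80 nm FWHM by
default), `r_j, z_j` scatterer reflectivities and depths, `n = 1.33` the
tissue index, `theta(k) = a2 (k-k0)^2 + a3 (k-k0)^3` the injected residual
dispersion, `FP` a fixed spectral pattern, and `k_m` the sampled wavenumbers.
Sampling nonlinearity is a monotone quadratic warp of the sample index
(`chirp` coefficient, |chirp| < 1). The sampled band spans 3× the FWHM
bandwidth, so the Gaussian envelope, not the band edge, sets the axial
point-spread function; the axial range follows from the sample spacing
(`z_max = pi / (2 n dk)`, about 454 µm for the 512-sample miniatures — the
hardware's 3.5 mm range corresponds to its own coarser wavenumber spacing).

Moving blood is modeled as axial random-walk jitter of the scatterers inside
vessel tubes: each repeat adds a Gaussian step of SD `sigma_flow`, giving
inter-repeat circular phase steps of SD `2 n k0 sigma_flow` — the default
`sigma_flow = lambda0 / (8n)` yields π/2, strong but not saturated phase
decorrelation. (A full re-draw of scatterer positions per repeat would pin
vessel phase variance at the uniform-phase limit π²/3 and erase the
dependence on flow magnitude.) Bulk eye motion is a per-B-scan axial
random walk (default step SD `lambda0/16`, i.e. 1.045 rad phase steps);
saccades decorrelate the speckle of affected B-scans (the beam samples
shifted tissue between repeats) and laterally displace all later positions.
No speckle correlation between adjacent A-scans, no amplitude decorrelation,
no multiple scattering, no fringe washout: the pipeline, not tissue optics,
is under test, and passing tests certify the contracts of the processing
chain, not realism of retinal images.

Fringes are scaled to 90% of full scale and quantized to 12-bit unsigned
samples, exercising the intensity-threshold path.

## Spectral reconstruction

`reconstruct_volume()` chains five steps, each exported separately:

* **Wavenumber calibration** (`calibrate_k`): the instantaneous phase of a
  single-reflector calibration fringe (k-clock) is extracted with the
  analytic-signal method, unwrapped, and smoothed by an envelope-weighted
  polynomial fit (degree 7, edges excluded — the one-sided-spectrum analytic
  signal carries boundary leakage that would otherwise violate sub-sample
  accuracy). Inverting the fitted phase onto a uniform grid gives the
  fractional-sample resampling map. A sweep whose instantaneous frequency
  collapses below 20% of its median is rejected as non-monotone (the phase
  *direction* of a real fringe is unobservable, so a fold manifests as a
  frequency zero, not a sign change).
* **Fixed-pattern removal**: the mean interference spectrum is estimated and
  subtracted per B-scan (not per volume), which also removes the
  non-interferometric DC line. For degenerate phantoms whose columns are
  identical (a mirror), this would cancel the signal itself; such fixtures
  disable the step.
* **Resampling** (`resample_to_k`): cubic-spline interpolation at the map
  positions, edge-clamped. Splines keep interpolation sidelobes below the
  apodized PSF sidelobes, where linear interpolation would not.
* **Dispersion compensation** (`compensate_dispersion`): multiplication of
  the analytic spectrum by `exp(-i theta(k))`. When coefficients are unknown,
  `optimize_dispersion()` minimizes the Shannon entropy of the normalized
  reconstructed intensity (sharpness metric) by a coarse grid over `a2`
  followed by Nelder–Mead over `(a2, a3)`; the shallowest 4% of depth pixels
  are excluded from the metric so the DC/envelope line cannot dominate it.
  `a3` is weakly identifiable under a Gaussian envelope (its phase is large
  only where the envelope is small); recovery contracts are asserted on `a2`.
* **Shaping and transform** (`shape_spectrum`, `fft_reconstruct`): unit-peak
  Hann apodization by default (first sidelobe −31.5 dB, ×1.6 main-lobe
  magnitude-FWHM cost versus rectangular), then zero-padding to 4× the sample
  count (the full-scale 1024 → 4096 configuration, preserved proportionally
  for miniatures) and a one-sided Fourier transform. Depth pixel 0 is zero
  path difference; the complex-conjugate ambiguity is left unresolved.

For a Gaussian envelope the magnitude PSF FWHM is
`(2 ln2 / pi) lambda0^2 / (n dlambda)` (≈ 4.7 µm here); the pipeline restores
a chirped, dispersed mirror fringe to within a few percent of this limit,
while skipping either correction leaves it ≥ 2× broader. The published 7 µm
axial resolution is a hardware figure and is not asserted.

## Phase-variance angiography

For the N repeats at one slow position, the N−1 wrapped inter-repeat phase
differences Δφ_i are corrected for bulk axial motion and squared:

```
PV(x, z) = (1 / (N-1)) * sum_i wrap(Δφ_i(x,z) - β_i(x))^2
```

**Centering.** The variance is computed about zero, not about the circular
mean of the corrected differences. For fully decorrelated phases the
zero-centered form has expectation π²/3 exactly, which is the calibration
property asserted in the tests; Monte-Carlo shows the circular-mean-centered
variant yields only ≈ 0.49 π²/3 for N = 5 (the mean soaks up a large share of
four dependent wrapped differences). The centered form remains available via
`center = "circular"`; with N = 2 it falls back to the zero-centered form.

**Bulk correction** (`bulk_phase_offset`): per A-scan column — axial bulk
motion varies along a B-scan in vivo, and per-column estimation is the
stricter contract — the mode of the intensity-weighted circular distribution
of Δφ is found by an averaged-shifted-histogram (64 bins over [−π, π), 4
shifts), then refined by intensity-weighted mean-shift iterations with a
triangular kernel spanning ±8 coarse bins. The soft kernel avoids the noise
amplification of hard truncation boundaries; the width admits concentrated
static phase while decorrelated flow pixels cannot displace the mode.
Intensity (magnitude-squared) weights approximate inverse phase variance.
Columns with fewer than 8 masked pixels inherit the nearest valid column's
offset. The estimator is idempotent to < 0.01 rad.

**Thresholding**: noise statistics (mean, SD of magnitude) come from a
structure-free band, by default the deepest 10% of the axial range; pixels
below `mu + 3 sigma` are excluded and their PV set to zero. Under Rayleigh
noise this excludes > 99% of pure-noise pixels.

Flow-projection artifacts (flow signal cast onto deeper layers) are
deliberately not removed, matching the processing chain being modeled.

## Flattening and en face projection

The RPE — the brightest posterior band — is segmented per A-scan as the
argmax of the median-smoothed intensity profile, with peak prominence as
confidence; columns below an adaptive prominence floor (10% of the median
prominence) are marked missing, emulating segmentation dropout over
geographic atrophy. A Zernike surface (OSA ordering, default radial order 4 =
15 terms) is fitted by least squares over the disk inscribed in the scan
field, corners extrapolated polynomially, with one round of 3×MAD outlier
rejection. Flattening shifts each A-scan by an *integer* pixel count
(`round(fitted) − reference`) with zero-fill at the edges — no axial
interpolation, so PV and intensity values are preserved exactly and the
operation round-trips bit-exactly away from the zero-filled margins.

After flattening, the global *en face* reference is the argmax of the
volume-mean axial intensity profile (the "RPE peak"). Whether this global
reference or the per-column segmentation is the right windowing origin is a
genuine ambiguity; the global convention is chosen and documented here.
Projection windows are specified in micrometres relative to that peak
(negative = anterior), converted through the axial pitch, and summed over the
half-open pixel interval — adjacent windows tile without double counting, and
the tiling conserves the full-depth sum. The three standard windows are
retina (−90 µm, 138 µm wide), choroid 1 (+12 µm, 28–39 µm) and choroid 2
(+127 µm, 120–180 µm); ranged widths default to their midpoint. The two
choroid windows fit only volumes with sufficient posterior range; the
miniature phantom pipeline defaults to the retina window.

BM-positions whose masked-pixel median PV exceeds `median + 5·MAD` across
positions are rejected as motion-corrupted and either dropped or
nearest-neighbour filled. Projections are filtered by a 3×3 median then a
σ = 1 px Gaussian — kernel sizes the underlying workflow left at ImageJ
defaults, exposed here as explicit configuration. Mosaicking registers tiles
by normalized cross-correlation around nominal offsets and feather-blends
overlaps linearly.

## Problem sizes and runtime choices

The test suite and acceptance script run the full chain on a 64 × 64-position,
5-repeat, 512-sample miniature (≈ 100 MB of complex data, tens of seconds),
with 32-position variants for the saccade and bulk-motion studies and a
32 × 32 delta-thin curved-RPE phantom for flattening accuracy. The phase-
variance calibration uses 10^5 Monte-Carlo pixels. These sizes make the
whole verification cycle a few minutes on one core while keeping every
statistical tolerance comfortably resolved.

## Known limitations

* The simulator's phase-only flow model cannot calibrate PV against absolute
  flow velocity; no velocity claims are made or tested.
* Sensitivity roll-off, fringe washout at megahertz sweep rates, beam focus
  and speckle statistics are not modeled; quantitative image-quality claims
  about real instruments are out of scope.
* The uncorrected vessel/static contrast on the miniature retina is ≈ 2.3:
  bounded below by the ratio of wrapped-normal variances of combined
  flow+bulk steps to bulk-only steps (≈ 2.4 ideal at the default motion
  magnitudes) — bulk correction improves contrast ≈ 25×, but an uncorrected
  ratio below 2 would require stronger bulk motion than the modeled
  conditions.
* `optimize_dispersion` assumes a single global coefficient pair per volume;
  depth-dependent dispersion is not modeled.
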