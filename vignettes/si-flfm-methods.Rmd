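---
title: "Structured-illumination Fourier light-field microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured-illumination Fourier light-field microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siflfm)
```

## The imaging problem

Fourier light-field microscopy (FLFM) places a microlens array (MLA) in a
Fourier plane of the detection path, so that each lenslet intercepts one
sub-region of the objective pupil and forms its own *view* of the sample
on a shared camera. A single exposure therefore carries multi-view
parallax, and a 3D volume can be reconstructed from one frame. The price
is that every view integrates fluorescence over the whole depth of field:
in scattering tissue the out-of-focus background can exceed the in-focus
signal several-fold and bury the structures of interest.

Structured illumination (SI) fixes this without sacrificing frame rate. A
digital micromirror device (DMD), conjugated to the native object plane
(NOP), projects a sinusoidal fringe pattern that is phase-stepped by
$2\pi/3$ between consecutive camera frames. Only light originating near
the NOP is modulated by the fringes; defocused fluorescence sees a
washed-out (uniform) illumination. Demodulating phase triplets therefore
removes the background before 3D reconstruction.

This package implements the full computational chain — optics derivation,
per-view PSF synthesis, a linear forward camera model, phantom
generators, three-phase optical sectioning with interleaved windows,
multi-view Richardson–Lucy (RL) deconvolution, PSF/resolution
calibration, and evaluation metrics — so the method can be built, tested
and benchmarked entirely on synthetic data.

## Optical model

`derive_system_parameters()` turns declared hardware values into system
parameters. With the shipped reference configuration (objective
$f = 7.2$ mm / NA 1.05 water immersion, tube lens $f = 200$ mm, Fourier
lens $f = 300$ mm, MLA pitch 3 mm and $f = 38.24$ mm):

* intermediate magnification $M_1 = f_{tube}/f_{obj} = 27.78\times$;
* total magnification $M = M_1 f_{mla}/f_{fourier} = 3.54\times$;
* per-view NA $= d_{mla} f_{tube} / (2 f_{obj} f_{fourier}) = 0.139$;
* pupil image diameter at the MLA
  $= 2\,\mathrm{NA}\, f_{obj} f_{fourier}/f_{tube} = 22.68$ mm.

`generate_view_layout()` packs lenslets hexagonally so each sub-aperture
lies wholly inside the pupil image. The geometry admits 37 lenses; the
reference instrument uses 31 views, which the layout honours by an
explicit truncation override that drops the outermost ring fragment (the
count is not derivable from the printed geometry alone, so it is
config-driven).

The DMD (1920×1080, 10.8 µm micromirrors — a datasheet constant, not a
printed one) reaches the sample through relays with a combined scale of
$0.072 = (300/150)\times(7.2/200)$, giving a projected extent of
1493 µm × 840 µm and a fringe period at the sample of
$90 \times 10.8 \times 0.072 = 69.98$ µm for the 90-pixel DMD pattern.

### PSF synthesis

`synthesize_psf_bank()` uses a scalar Fourier-optics model: view $v$ has
a circular sub-aperture of radius $\mathrm{NA}_{view}$ centred at pupil
offset $c_v$, and the amplitude PSF at depth $z$ is the Fourier transform
of the aperture with the propagation phase
$\exp\!\big(i\,2\pi z \sqrt{n^2 - |u|^2}/\lambda\big)$ evaluated at the
*absolute* pupil coordinate $u = c_v + u'$ ($n = 1.33$, water). The tilt
component of that phase is what produces the depth-proportional lateral
shift (parallax) of off-centre views — the information RL triangulates
into depth. A quadratic (paraxial) defocus option exists; the exact phase
is the default. Aberrations, vector effects and polarization are out of
scope.

PSFs are normalized jointly per depth (`sum over views and pixels = 1`),
so a point source of intensity $S$ at the NOP projects to a frame of
total intensity $S$. For extended sources a small part of the Airy tails
falls outside the finite sub-image crop, so energy conservation holds to
about $10^{-3}$ on the small grids used here — exactly at the centre,
as the tests assert.

Simulated banks carry a compact *mosaic* sensor layout (views tiled on a
near-square grid of non-overlapping sub-images): parallax lives in the
PSFs, not in the sensor placement, so this keeps simulated frames small.
The physical sub-image centres of the full-scale instrument remain
available from the layout.

## Sectioning algorithm

With fringe phases $0, 2\pi/3, 4\pi/3$, a pixel records
$I_k = B + A \sin(\theta + 2\pi k/3)$, where $B$ carries the out-of-focus
light plus the unmodulated half of the in-focus excitation and $A$ is the
modulated in-focus amplitude. The demodulation

$$I_{OS} = \sqrt{(I_1-I_2)^2 + (I_1-I_3)^2 + (I_2-I_3)^2}$$

cancels $B$ identically and evaluates to $(3/\sqrt2)\,A$ for any global
phase $\theta$. `optical_section_triplet()` multiplies by $\sqrt2/3$ by
default so the output *is* $A$ — a deliberate deviation from the printed
root-sum-square, which keeps the sectioned image on the same amplitude
scale as the uniform image in the fusion step (a flag restores the raw
convention). When the simulated modulation depth $m_0 < 1$ is known it is
divided out for the same reason.

The pixel mean $(I_1+I_2+I_3)/3$ is the *uniform* image — exactly what a
conventional FLFM exposure would have recorded, which is why the package
uses it as the "plain FLFM" arm of every comparison.

### Fusion

The demodulated image rectifies noise and can carry residual
fringe-frequency artifacts; the uniform image has clean high frequencies
but hazy low frequencies. `rsim_fuse()` combines the two bands:
$LP(I_{OS}) + HP(I_{UI})$ with a single isotropic Gaussian transfer
$G(f) = \exp(-f^2/2\sigma^2)$, $HP = 1 - G$, so the pair sums to one at
every frequency. The cutoff is expressed as a fraction (default 0.5) of
the fringe frequency and $\sigma$ is set to half the cutoff, which puts
$G$ at $e^{-2}$ at the cutoff and below $4\times10^{-4}$ at the fringe
frequency itself — a pure fringe artifact is attenuated by more than two
orders of magnitude (asserted in the tests). The reference for this
choice is behavioural, not printed: no cutoff value is fixed by the
instrument, so it is an exposed parameter. Filtering runs on
mirror-padded images to suppress boundary ringing, per segmented view by
default (the pixelwise demodulation itself commutes with segmentation for
non-overlapping sub-images).

The fusion has a structural trade-off worth stating: any background
structure *above* the cutoff passes through $HP(I_{UI})$ into the fused
image. The method therefore assumes out-of-focus haze is smooth on the
scale of half a fringe period — true for diffuse scattered backgrounds,
and the regime the phantoms emulate. The tests pin both sides: exact
cancellation for the raw demodulation, and a bounded (≤ 5 %) re-admission
through the fused path on a structured background.

### Interleaved windows

Because the demodulation is invariant to the global phase, *any* three
consecutive frames of a $2\pi/3$-stepped sequence form a valid triplet.
`section_sequence()` therefore slides a three-frame window over the
sequence: $3n$ raw frames yield $3n-2$ sectioned frames instead of $n$,
and the effective volumetric rate equals the camera frame rate (40 Hz
instead of 13.3 Hz, or 5 Hz instead of 1.67 Hz) without acquiring a
single extra frame. Phase metadata is validated; a dropped frame
invalidates every window containing it and raises an error rather than
silently skipping.

## Reconstruction

`richardson_lucy_multiview()` implements the multiplicative
maximum-likelihood update for Poisson data,

$$x \leftarrow x \cdot \frac{\sum_v H_v^T\big(y_v / \max((Hx)_v,
\varepsilon)\big)}{\sum_v H_v^T 1},$$

with an FFT-based forward model zero-padded to the linear-convolution
size (circular wrap would alias the parallax shifts that encode depth)
and an adjoint that is exact to machine precision — the tests verify the
inner-product identity at $10^{-8}$ and the resulting monotonicity of the
Poisson log-likelihood, which is recorded per iteration. Numerical
choices: ratio guard $\varepsilon = 10^{-12}$; initialization from a flat
volume at the mean back-projected level (standard, unbiased); exactly
`n_iter` iterations with no early stopping, defaulting to 30 (no
iteration count is printed for the instrument; the default is declared,
not inferred).

## Calibration

On the real instrument the simulated PSF is not accurate enough for
reconstruction, so PSFs are measured from bead z-stacks.
`extract_psf_from_beads()` mirrors that procedure on synthetic data:
threshold at background median $+ 5\cdot$MAD (the extraction algorithm is
named for the instrument but no threshold is printed; the rule is a
declared default), keep the largest connected component (ties by total
intensity, then by centroid position), and crop a window that is *fixed
across depth*, centred on the component at the depth nearest focus —
centring per depth would erase the parallax shift the reconstruction
needs.

Resolution is quantified by FWHM of reconstructed beads
(`measure_fwhm()`: 1D profile through the peak, half-maximum crossings by
linear interpolation; "lateral" reports the mean of the x and y widths,
since the axis convention for the headline number is not fixed by the
instrument description). `loess_fit()` fits resolution against position
with locally weighted linear regression using a Gaussian distance kernel
$K_d(x_0,x_i) = \exp(-(x_0-x_i)^2/2d^2)$ over *all* points (not a
nearest-neighbour span — matching the estimator as specified rather than
classical LOESS), bandwidth $d = 10$ µm, spread
$\sigma_{x_0} = \sqrt{F/\sum_i K_d}$ from the weighted residuals with no
degrees-of-freedom correction, and a 95 % band at $\pm 2\sigma$.

## What the phantoms emulate — and what they do not

The generators are pure functions of (parameters, seed) and always emit
their ground truth.

* `make_bead_field()`: spheres rendered by sub-voxel overlap fractions
  ($4^3$ samples per voxel); sub-voxel beads degrade to a single-voxel
  impulse with a warning. An optional minimum separation (rejection
  sampling) models dilutions sparse enough that beads are individually
  resolvable.
* `make_neuron_scene()`: somata of 6–12 µm with Poisson event trains
  convolved with a one-compartment calcium kernel (1-frame rise,
  $\tau = 1.6$ s decay at the configured volume rate). Real indicator
  kinetics are richer; the phantom only needs plausible temporal
  structure.
* `make_flowing_cell()`: one sphere on a constant-speed helix (or line)
  with per-frame ground-truth positions.
* `make_background()`: a positive low-pass random field confined to
  depths beyond a stated defocus and scaled to an exact
  background-to-signal ratio.

None of the phantoms model tissue scattering, aberrations, or indicator
photophysics. Passing the simulation benchmarks therefore demonstrates
the *algorithmic* chain — demodulation exactness, count laws, model-true
deconvolution — not performance on real tissue, where PSF mismatch and
scattering degrade both arms of every comparison.

## Benchmark scenes and problem sizes

Two packaged benchmarks (`bead_resolution_benchmark()`,
`background_suppression_benchmark()`) regenerate the package's headline
numbers from scratch; `scripts/acceptance.R` runs exactly these.

**Resolution.** A noise-free 1.1 µm bead at the NOP, imaged through the
full 31-view reference bank and reconstructed with 30 RL iterations. The
grid is 63 × 63 pixels per view at the native 1.27 µm object-space pitch
(an 80 µm field) over ±15 µm in 1.5 µm steps — a deliberately scaled-down
axial range chosen so the whole reconstruction runs in tens of seconds;
near focus it leaves the measured widths unaffected. With a matched,
noise-free forward model RL converges far below the instrument's measured
2–4 µm lateral / 4–10 µm axial envelope; the benchmark checks the
envelope as an upper bound.

**Background suppression.** Twenty in-focus beads under a 5× out-of-focus
background with Poisson noise at 1000 photons per intensity unit,
processed both ways (sectioned vs. triplet mean) and compared by median
SBR over all 20 ROIs, $SBR = (\bar I_{ROI} - \bar I_{ann})/\bar
I_{ann}$ with the lower-of-two-middles median convention. The SBR
formula itself is a declared operational choice (none is printed for the
instrument), which is why the benchmark's acceptance surface is the
*fold improvement*, not absolute medians. Four scene choices required
genuine design decisions, each made once for physical realism:

1. The haze sits at 20–35 µm depth, *outside* the reconstructed ±15 µm
   range. If the background is placed inside a model-matched
   reconstruction volume, RL assigns it to its true depth and plain FLFM
   spuriously matches the sectioned arm — an inverse crime. Out-of-range
   background is what the real instrument faces: haze originates across
   hundreds of microns while reconstruction spans the DOF.
2. Beads are drawn with an 18 µm minimum separation so each ROI's
   annulus (3–6 voxels) measures background, not a neighbouring bead.
3. Bead brightness is 2000 intensity units, so the fixed photon scale of
   1000 yields genuinely *mild* shot noise (thousands of photons at a
   bead peak), as beads are in practice far brighter than tissue haze.
4. The fringe period is 20 µm on the ~100 µm desk-scale field,
   preserving the full-scale instrument's fringe-to-field ratio
   (70 µm : 840 µm ≈ 12 periods). Using the full-scale 70 µm period on a
   100 µm field would push the fusion cutoff below the field size and let
   the high-pass re-admit the haze — a pure artifact of miniaturization.

## Degenerate inputs and tie-breaks

Sub-pixel view centres are rejected in simulation (stamping is
integer-pixel; calibration handles real sub-pixel centres by cropping
only). Out-of-bounds crops error instead of zero-padding. All-zero data
reconstructs to a zero volume with a warning; NaNs are errors. Peak ties
in centre calibration and component ties in PSF extraction break by
intensity, then (row, column). Medians use the lower of two middles.
Seeded generators save and restore the caller's RNG state.

## Known limitations

* The scalar PSF model omits aberrations; on the real instrument
  calibrated PSFs replace simulated ones precisely because of this.
* 32-bit TIFF output is quantized by the writer to $2^{-32}$ of the
  recorded power-of-two scale — lossless for display and analysis
  purposes, but not bit-identical for arbitrary doubles.
* Sectioning assumes the phase step is exactly $2\pi/3$ and known;
  phase estimation from data is out of scope.
* The noise-free, model-matched benchmarks measure algorithmic
  correctness. Resolution and SBR numbers on real data depend on
  calibration quality and scattering, and will be worse.
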