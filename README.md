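# siflfm

Simulation and reconstruction for **structured-illumination Fourier
light-field microscopy (SI-FLFM)** in R.

Fourier light-field microscopy forms simultaneous multi-view images of a
3D sample by placing a microlens array in a Fourier plane: one camera
exposure carries enough parallax to reconstruct a volume. Its weakness in
scattering tissue is out-of-focus background, which can exceed the
in-focus signal several-fold. SI-FLFM projects sinusoidal illumination
fringes phase-stepped by 2π/3 between frames; only in-focus fluorescence
is modulated, so a three-phase demodulation

    I_OS = sqrt((I1−I2)² + (I1−I3)² + (I2−I3)²)

removes the background before reconstruction. Because any three
*consecutive* frames form a valid triplet, a sliding window extracts
**3n−2 sectioned frames from 3n raw frames** — optical sectioning without
losing frame rate (40 Hz instead of 13.3 Hz at a 40 Hz camera). Each
sectioned frame is segmented into per-view sub-images and reconstructed
into a volume by multi-view Richardson–Lucy deconvolution

    x ← x · [ Σ_v H_vᵀ ( y_v / (H x)_v ) ] / [ Σ_v H_vᵀ 1 ]

against a per-view, per-depth PSF bank (synthesized by scalar
diffraction, or calibrated from bead z-stacks). Refined-SIM fusion
`LP(I_OS) + HP(I_UI)` suppresses fringe artifacts and demodulation noise,
resolution is profiled by bead FWHM with locally weighted regression
(Gaussian kernel, 95% bands), and evaluation covers signal-to-background
ratio (SBR) statistics, ΔF/F traces and 3D centroid tracking. Seeded
phantom generators (bead fields, firing neurons, a flowing blood cell,
diffuse background) make the whole chain testable without a microscope.

The package is written for microscopists and methods developers who want
a desk-checkable implementation of the SI-FLFM processing chain.

## Worked example

```r
library(siflfm)

cfg <- default_optical_config()        # 31-view reference instrument
der <- derive_system_parameters(cfg)
der
#> Derived FLFM optics
#>   intermediate magnification : 27.78x
#>   total magnification        : 3.54x
#>   per-view NA                : 0.139
#>   pupil image at MLA         : 22.68 mm
#>   field of view              : 847 um
#>   DMD projected extent       : 1493 x 840 um
#>   fringe period at sample    : 69.98 um
#>   object-space pixel pitch   : 1.271 um
```

A 27.78× intermediate image is demagnified to 3.54× total; each of the 31
microlens views images at NA 0.139, and the DMD's projected footprint
(1493 × 840 µm) covers the full field of view.

Simulate, section and reconstruct a small bead scene:

```r
cfg$n_views_requested <- 7L; cfg$z_range <- 12; cfg$z_step <- 3
der <- derive_system_parameters(cfg)
lay <- generate_view_layout(der, cfg)
bank <- synthesize_psf_bank(cfg, der, lay, c(33, 33), pitch = 1.8)

ph  <- make_bead_field(3, c(33, 33, 5), c(1.8, 1.8, 3),
                       bead_diameter_um = 3, seed = 1, z_range_um = c(0, 0))
pat <- illumination_pattern(m0 = 1, contrast_model = "eq5_ideal",
                            fringe_period_um = 15)
raw <- simulate_si_sequence(ph, bank, pat, n_frames = 6)
sect <- section_sequence(raw)
length(sect)
#> [1] 4                      # 6 raw frames -> 4 sectioned (n - 2)
vols <- reconstruct_sequence(sect, bank, n_iter = 15)
vols[[1]]
#> FLFM volume: 33 x 33 x 5 voxels @ (1.8, 1.8, 3) um, total 4.533
#>   RL iterations: 15, final Poisson log-likelihood -21.2255
```

Six phase-stepped frames yield four sectioned frames (the two interleaved
windows straddling the period boundary are the "free" ones), each of
which reconstructs into a 3D volume whose total intensity matches the
phantom's in-focus signal.

An end-to-end seeded pipeline with on-disk artifacts (TIFF volumes, CSV
tables, JSON manifest):

```r
run_demo_pipeline("beads", seed = 2, outdir = "demo_out")
#> $n_raw_frames 6, $n_sectioned 4, $n_volumes 4,
#> $sbr_improvement_factor 5.18, ...
```

A thin CLI over the same functions is installed at
`inst/cli/siflfm.R` (subcommands `simulate`, `calibrate-centers`,
`section`, `reconstruct`, `demo`).

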