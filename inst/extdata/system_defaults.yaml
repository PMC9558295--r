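# Reference SI-FLFM instrument: 25x/1.05 water objective behind a 200 mm tube
# lens, 300 mm Fourier lens, 3 mm-pitch MLA, DLP9500 DMD projecting 90-pixel
# sinusoidal fringes. illum_relay_magnification is the DMD->sample scale,
# (300/150) * (7.2/200) = 0.072.
f_objective: 7.2          # mm
na_objective: 1.05
f_tube: 200.0             # mm
f_fourier: 300.0          # mm
f_mla: 38.24              # mm
d_mla: 3.0                # mm
emission_wavelength: 525.0    # nm
excitation_wavelength: 470.0  # nm
camera_pixel_pitch: 4.5   # um
dmd_pixels: [1920, 1080]
dmd_pixel_pitch: 10.8     # um (DLP9500 datasheet)
illum_relay_magnification: 0.072
fringe_period_dmd: 90     # DMD pixels
n_views_requested: 31
z_range: 90.0             # um
z_step: 1.5               # um
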