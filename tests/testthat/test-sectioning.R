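test_that("root-sum-square demodulation recovers the closed-form amplitude", {
  # B = 10, S = 4, theta = pi/2 at every pixel:
  # (I1, I2, I3) = (14.0000, 6.5359, 9.4641); the classic printed example
  # uses theta = 0 -> (10.0000, 13.4641, 6.5359)
  tr <- phase_pixels(10, 4, 0)
  expect_equal(tr[[1L]][1L], 10, tolerance = 1e-9)
  expect_equal(tr[[2L]][1L], 13.4641, tolerance = 1e-4)
  expect_equal(tr[[3L]][1L], 6.5359, tolerance = 1e-4)
  raw <- optical_section_triplet(tr, normalized = FALSE)
  expect_equal(raw[1L], sqrt(72), tolerance = 1e-9)        # 8.4853
  expect_equal(optical_section_triplet(tr)[1L], 4, tolerance = 1e-9)
})

test_that("demodulation is exact and phase-invariant over (B, S, phi)", {
  for (B in c(0, 3, 50)) for (S in c(0.5, 2)) {
    outs <- vapply(seq(0, 2 * pi, length.out = 100L), function(phi)
      optical_section_triplet(phase_pixels(B, S, phi))[1L], numeric(1))
    expect_true(all(abs(outs - S) < 1e-9 * max(1, S)))
    expect_lt(diff(range(outs)) / S, 1e-9)
  }
})

test_that("unmodulated input demodulates to zero", {
  m <- matrix(5, 4L, 4L)
  expect_true(all(optical_section_triplet(list(m, m, m)) == 0))
  expect_error(optical_section_triplet(list(m, m, matrix(5, 3L, 3L))),
               "shape")
})

test_that("the uniform image is the triplet mean (DC only)", {
  tr <- phase_pixels(10, 4, 0)
  expect_equal(uniform_from_triplet(tr)[1L], 10, tolerance = 1e-9)
  z <- matrix(0, 2L, 2L)
  expect_true(all(uniform_from_triplet(list(z, z, z)) == 0))
})

test_that("low-pass and high-pass transfers are exactly complementary", {
  tf <- rsim_transfer(c(64L, 48L), fringe_freq_px = 0.1)
  expect_lt(max(abs(tf$lp + tf$hp - 1)), 1e-12)
  expect_true(all(tf$lp >= 0 & tf$lp <= 1))
  expect_error(rsim_transfer(c(64L, 64L), fringe_freq_px = 1.2), "Nyquist")
  expect_error(rsim_transfer(c(64L, 64L), 0.1, cutoff_fraction = 1.5),
               "cutoff_fraction")
})

test_that("fusion attenuates a fringe-frequency artifact by over 100x", {
  n <- 64L
  f_m <- 8 / n                                   # exact FFT bin
  x <- (seq_len(n) - 1)
  artifact <- 0.5 * outer(rep(1, n), sin(2 * pi * f_m * x))
  base <- matrix(10, n, n)
  fused <- rsim_fuse(base + artifact, base, fringe_freq_px = f_m)
  amp_at <- function(img) {
    sp <- Mod(stats::fft(img))
    sp[1L, 9L]                                   # (0, f_m) bin
  }
  expect_lt(amp_at(fused - base) / amp_at(artifact), 0.01)
})

test_that("fusion passes a band-limited in-focus scene almost unchanged", {
  # zero out-of-focus light, full modulation: OS == UI == scene, so the
  # fused result must match the scene up to boundary effects
  n <- 48L
  sc <- siflfm:::gauss_blur2(matrix(stats::rexp(n * n), n), 3) + 1
  fused <- rsim_fuse(sc, sc, fringe_freq_px = 0.2)
  expect_lt(sqrt(sum((fused - sc)^2) / sum(sc^2)), 1e-9)
})

test_that("sliding windows implement the 3n - 2 count law", {
  expect_identical(interleaved_windows(3L), cbind(1L, 2L, 3L))
  expect_identical(nrow(interleaved_windows(6L)), 4L)
  for (k in 1:5)
    expect_identical(nrow(interleaved_windows(3L * k)), 3L * k - 2L)
  expect_error(interleaved_windows(2L), "at least 3")
})

bank <- tiny_bank()

test_that("sectioning a static noiseless sequence gives identical frames", {
  np <- dim(bank$psfs)[1L]; nz <- dim(bank$psfs)[3L]
  der <- derive_system_parameters(tiny_config())
  pat <- illumination_pattern(m0 = 1, contrast_model = "eq5_ideal",
                              fringe_period_um = 15)
  iz0 <- which(bank$z_grid == 0)
  ph <- suppressWarnings(make_bead_field(
    3L, c(np, np, nz), c(1.8, 1.8, 3), bead_diameter_um = 4, seed = 2,
    z_range_um = c(0, 0)))
  raw <- simulate_si_sequence(ph, bank, pat, 6L)
  sect <- section_sequence(raw)
  expect_length(sect, 4L)
  expect_identical(vapply(sect, function(s) s$timestamp, integer(1)),
                   2:5)
  ref <- sect[[1L]]$image
  for (s in sect[-1L])
    expect_lt(max(abs(s$image - ref)) / max(ref), 1e-9)
  # the sectioned frame equals the in-focus-only projection
  infocus <- project_volume(ph$volume, bank)
  expect_lt(max(abs(ref - infocus)) / max(infocus), 0.02)
})

test_that("sectioning removes an unmodulated background almost entirely", {
  np <- dim(bank$psfs)[1L]; nz <- dim(bank$psfs)[3L]
  pat <- illumination_pattern(m0 = 1, contrast_model = "eq5_ideal",
                              fringe_period_um = 15)
  sig <- suppressWarnings(make_bead_field(
    3L, c(np, np, nz), c(1.8, 1.8, 3), bead_diameter_um = 4, seed = 2,
    z_range_um = c(0, 0)))
  bg <- make_background(c(np, np, nz), c(1.8, 1.8, 3), strength = 5,
                        signal_total = sum(sig$volume),
                        correlation_length_um = 30, z_exclude_um = 2,
                        seed = 3)
  scene <- sig$volume + bg$volume
  raw <- simulate_si_sequence(scene, bank, pat, 3L)
  raw_sig <- simulate_si_sequence(sig$volume, bank, pat, 3L)
  bg_frame <- project_volume(bg$volume, bank)
  # the demodulation itself cancels unmodulated light exactly
  os <- section_sequence(raw, fuse = FALSE)[[1L]]$image
  os_sig <- section_sequence(raw_sig, fuse = FALSE)[[1L]]$image
  expect_lt(sum(abs(os - os_sig)) / sum(bg_frame), 1e-6)
  # the fused image re-admits a little background through the uniform
  # image's high-pass band (a documented trade-off of the fusion)
  sect <- section_sequence(raw)[[1L]]$image
  sig_only <- section_sequence(raw_sig)[[1L]]$image
  expect_lt(sum(abs(sect - sig_only)) / sum(bg_frame), 0.05)
})

test_that("non-uniform phase stepping is rejected, naming the frame", {
  np <- dim(bank$psfs)[1L]; nz <- dim(bank$psfs)[3L]
  pat <- illumination_pattern(m0 = 1, fringe_period_um = 15)
  raw <- simulate_si_sequence(array(1e-3, c(np, np, nz)), bank, pat, 6L)
  raw$phase_index <- c(0L, 1L, 2L, 4L, 5L, 6L)   # a dropped frame
  expect_error(section_sequence(raw), "frame 3")
})

test_that("modulation-depth rescaling restores the uniform amplitude scale", {
  for (m0 in c(1, 0.6)) {
    tr <- phase_pixels(8, 2 * m0, 0.3)   # amplitude = S * m0 with S = 2
    raw <- list(frames = tr, phase_index = 0:2, fringe_freq_px = 0.2,
                m0 = m0, phase_offset = 0, contrast_model = "eq5_ideal",
                view_centers = NULL, sub_shape = NULL)
    class(raw) <- "raw_sequence"
    out <- section_sequence(raw, fuse = FALSE)[[1L]]$image
    expect_equal(out[1L], 2, tolerance = 1e-9)
  }
})
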