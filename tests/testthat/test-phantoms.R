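test_that("bead fields are pure functions of (parameters, seed)", {
  a <- make_bead_field(10L, c(32L, 32L, 8L), c(1, 1, 2), seed = 3)
  b <- make_bead_field(10L, c(32L, 32L, 8L), c(1, 1, 2), seed = 3)
  expect_identical(a$volume, b$volume)
  expect_identical(a$emitters, b$emitters)
  c <- make_bead_field(10L, c(32L, 32L, 8L), c(1, 1, 2), seed = 4)
  expect_false(identical(a$volume, c$volume))
  # generators must not disturb the caller's RNG stream
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(make_bead_field(3L, c(16L, 16L, 4L), c(1, 1, 2),
                                          seed = 1))
  expect_identical(stats::runif(1), before)
})

test_that("a centred bead renders as a symmetric sphere of the right mass", {
  ph <- make_bead_field(1L, c(21L, 21L, 21L), c(1, 1, 1),
                        bead_diameter_um = 6,
                        centers_um = matrix(0, 1L, 3L))
  v <- ph$volume
  expect_equal(v, v[21:1, , ], tolerance = 1e-12)
  expect_equal(v, aperm(v, c(2, 1, 3)), tolerance = 1e-12)
  # total intensity ~ sphere volume / voxel volume
  expect_equal(sum(v), 4 / 3 * pi * 3^3, tolerance = 0.02)
})

test_that("sub-voxel beads fall back to a single-voxel impulse", {
  expect_warning(
    ph <- make_bead_field(1L, c(9L, 9L, 5L), c(2, 2, 3),
                          bead_diameter_um = 1.1,
                          centers_um = matrix(0, 1L, 3L)),
    "impulse")
  expect_equal(sum(ph$volume > 0), 1L)
})

test_that("bead count matches a labelling oracle on the rendered volume", {
  skip_if_not_installed("igraph")
  ph <- make_bead_field(50L, c(96L, 96L, 24L), c(1, 1, 2),
                        bead_diameter_um = 3, seed = 12,
                        min_separation_um = 6)
  mask <- ph$volume > 0.5 * max(ph$volume)
  expect_equal(component_count_oracle(mask), 50)
})

test_that("minimum bead separation is honoured", {
  ph <- make_bead_field(15L, c(64L, 64L, 8L), c(1, 1, 2), seed = 5,
                        bead_diameter_um = 2, min_separation_um = 9)
  dmin <- min(stats::dist(as.matrix(ph$emitters[, c("y_um", "x_um",
                                                    "z_um")])))
  expect_gte(dmin, 9)
  expect_error(make_bead_field(200L, c(16L, 16L, 4L), c(1, 1, 1), seed = 1,
                               min_separation_um = 10),
               "minimum separation")
})

test_that("calcium traces superpose kernel responses exactly", {
  nfr <- 60L
  ev <- list(c(5L, 9L, 30L), integer(0), 40L)
  ph <- make_neuron_scene(3L, c(32L, 32L, 8L), c(2, 2, 3),
                          firing_rate_hz = 1, frame_rate_hz = 10,
                          duration_frames = nfr, seed = 2,
                          event_times = ev, amplitude = 0.7)
  kern <- calcium_kernel(nfr, 10, 1, 1.6)
  # direct superposition oracle
  for (n in 1:3) {
    want <- numeric(nfr)
    for (te in ev[[n]])
      for (j in te:nfr) want[j] <- want[j] + 0.7 * kern[j - te + 1L]
    expect_equal(ph$traces[, n], want, tolerance = 1e-12)
  }
  # single event: peak at the event frame, monotone decay after
  tr3 <- ph$traces[, 3L]
  expect_identical(which.max(tr3), 40L)
  expect_true(all(diff(tr3[40:nfr]) < 0))
  # silent neuron: flat zero trace
  expect_true(all(ph$traces[, 2L] == 0))
})

test_that("zero firing rate gives constant baseline volumes", {
  ph <- make_neuron_scene(2L, c(24L, 24L, 6L), c(2, 2, 3),
                          firing_rate_hz = 0, frame_rate_hz = 10,
                          duration_frames = 20L, seed = 8)
  expect_true(all(ph$traces == 0))
  expect_identical(phantom_volume(ph, 1L), phantom_volume(ph, 17L))
})

test_that("flowing-cell paths have constant speed and rate-scaled sampling", {
  shape <- c(48L, 48L, 16L); vp <- c(1.5, 1.5, 2)
  lin <- make_flowing_cell(shape, vp, speed_um_per_s = 30,
                           frame_rate_hz = 10, n_frames = 12L,
                           path = "line",
                           path_spec = list(start_um = c(0, -20, 0),
                                            direction = c(0, 1, 0)))
  steps <- diff(lin$positions$x_um)
  expect_equal(steps, rep(3, 11L), tolerance = 1e-12)
  # zero speed: static
  still <- make_flowing_cell(shape, vp, 0, 10, 5L, path = "line",
                             path_spec = list(start_um = c(0, 0, 0),
                                              direction = c(0, 1, 0)))
  expect_equal(diff(still$positions$x_um), rep(0, 4L))
  # 40 Hz observes 3x the positions of 13.33 Hz over the same duration
  dur <- 0.6
  fast <- make_flowing_cell(shape, vp, 20, 40, as.integer(40 * dur),
                            path_spec = list(radius_um = 8, pitch_um = 20))
  slow <- make_flowing_cell(shape, vp, 20, 40 / 3, as.integer(40 / 3 * dur),
                            path_spec = list(radius_um = 8, pitch_um = 20))
  expect_identical(nrow(fast$positions), 3L * nrow(slow$positions))
  # helix steps are equal (constant-speed parametrisation); the chord is
  # marginally shorter than the 0.5 um arc
  hstep <- sqrt(rowSums(apply(fast$positions[, c("y_um", "x_um", "z_um")],
                              2L, diff)^2))
  expect_lt(diff(range(hstep)), 1e-12)
  expect_equal(mean(hstep), 20 / 40, tolerance = 1e-3)
  expect_warning(make_flowing_cell(shape, vp, 200, 10, 3L, path = "line",
                                   path_spec = list(start_um = c(0, -25, 0),
                                                    direction = c(0, 1, 0)),
                                   sub_image_extent_um = 30),
                 "alias")
})

test_that("background fields realise the requested strength off focus", {
  shape <- c(32L, 32L, 9L); vp <- c(2, 2, 3)
  z0 <- make_background(shape, vp, strength = 0, seed = 1)
  expect_true(all(z0$volume == 0))
  bg <- make_background(shape, vp, strength = 5, signal_total = 12,
                        z_exclude_um = 4, seed = 1)
  expect_equal(sum(bg$volume) / 12, 5, tolerance = 1e-9)
  expect_true(all(bg$volume >= 0))
  # planes within the exclusion stay empty (|z| <= 4 um -> planes 4:6)
  expect_true(all(bg$volume[, , 4:6] == 0))
  expect_gt(sum(bg$volume[, , 1L]), 0)
})

test_that("longer correlation lengths shift background power to lower
           frequencies", {
  shape <- c(64L, 64L, 5L); vp <- c(1, 1, 3)
  centroid_freq <- function(corr) {
    bg <- make_background(shape, vp, strength = 1, seed = 9,
                          correlation_length_um = corr, z_exclude_um = 2)
    pl <- bg$volume[, , 1L]
    ps <- Mod(stats::fft(pl - mean(pl)))^2
    f <- sqrt(outer(siflfm:::fft_freq(64)^2, siflfm:::fft_freq(64)^2, `+`))
    sum(f * ps) / sum(ps)
  }
  cf <- vapply(c(2, 4, 8), centroid_freq, numeric(1))
  expect_true(all(diff(cf) < 0))
})
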