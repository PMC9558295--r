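make_roi_vol <- function(dims = c(21L, 21L, 9L), roi_val = 20, bg_val = 10) {
  vol <- array(bg_val, dims)
  roi <- roi_spec(c(11, 11, 5), 2, 4, 7)
  m <- siflfm:::roi_masks(dims, roi)
  vol[m$roi] <- roi_val
  list(vol = vol, roi = roi)
}

test_that("SBR is the contrast over the local annulus", {
  x <- make_roi_vol(roi_val = 20, bg_val = 10)
  expect_equal(compute_sbr(x$vol, x$roi), 1)
  flat <- make_roi_vol(roi_val = 10, bg_val = 10)
  expect_equal(compute_sbr(flat$vol, flat$roi), 0)
  # monotone in ROI brightness, invariant under global scaling
  sbrs <- vapply(c(15, 30, 90), function(v)
    compute_sbr(make_roi_vol(roi_val = v)$vol, x$roi), numeric(1))
  expect_true(all(diff(sbrs) > 0))
  expect_equal(compute_sbr(7.3 * x$vol, x$roi), compute_sbr(x$vol, x$roi),
               tolerance = 1e-12)
  zero <- array(0, c(21L, 21L, 9L))
  expect_error(compute_sbr(zero, x$roi), "not positive")
  expect_error(roi_spec(c(5, 5, 5), 3, 2, 6), "annulus_inner")
  expect_error(roi_spec(c(5, 5, 5), 2, 4, 3), "annulus_outer")
})

test_that("median statistics use the lower-of-two-middles convention", {
  x <- make_roi_vol()
  rois <- list(x$roi, roi_spec(c(11, 11, 5), 2, 4, 7),
               roi_spec(c(10, 10, 5), 2, 4, 7),
               roi_spec(c(12, 12, 5), 2, 4, 7))
  st <- sbr_statistics(x$vol, x$vol, rois)
  expect_equal(st$improvement_factor, 1)
  expect_identical(siflfm:::median_low(c(4, 1, 3, 2)), 2)
  expect_identical(siflfm:::median_low(c(5, 1, 3)), 3)
  expect_error(sbr_statistics(x$vol, x$vol, list()), "empty")
})

test_that("dF/F traces are zero for constant series and scale-invariant", {
  x <- make_roi_vol()
  series <- rep(list(x$vol), 12L)
  tr <- dff_traces(series, list(x$roi))
  expect_true(all(tr == 0))
  expect_error(dff_traces(series[1:5], list(x$roi)), "10 time points")
  # a transient peaks at its ground-truth frame
  series2 <- lapply(1:12, function(t) x$vol * (1 + 0.5 * (t == 7)))
  tr2 <- dff_traces(series2, list(x$roi))
  expect_identical(which.max(tr2[, 1L]), 7L)
  expect_equal(max(tr2), 0.5, tolerance = 1e-9)
  # invariance under global intensity scaling
  tr3 <- dff_traces(lapply(series2, `*`, 40), list(x$roi))
  expect_equal(tr3, tr2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(dff_traces(rep(list(0 * x$vol), 12L), list(x$roi)),
               "F0")
})

test_that("finer temporal sampling separates close transients", {
  # two events 2 base-frames apart merge at 1/3 sampling but resolve at
  # full rate
  base_rate <- 30
  ev <- list(c(31L, 33L))
  ph_fast <- make_neuron_scene(1L, c(16L, 16L, 4L), c(2, 2, 3),
                               frame_rate_hz = base_rate,
                               duration_frames = 90L, seed = 1,
                               event_times = ev, decay_tau_s = 0.15)
  tr_fast <- ph_fast$traces[, 1L]
  n_peaks <- function(tr) sum(diff(sign(diff(tr))) == -2)
  expect_identical(n_peaks(tr_fast), 2L)
  tr_slow <- tr_fast[seq(1L, 90L, by = 3L)]
  expect_lt(n_peaks(tr_slow), 2L)
})

test_that("centroid tracking follows a helix within a voxel", {
  shape <- c(40L, 40L, 12L); vp <- c(1.5, 1.5, 2)
  ph <- make_flowing_cell(shape, vp, speed_um_per_s = 24,
                          frame_rate_hz = 20, n_frames = 10L,
                          cell_diameter_um = 5,
                          path_spec = list(radius_um = 6, pitch_um = 18))
  series <- lapply(1:10, function(t) phantom_volume(ph, t))
  start <- c(ph$positions$y_um[1L] / 1.5 + 21,
             ph$positions$x_um[1L] / 1.5 + 21,
             ph$positions$z_um[1L] / 2 + 7)
  track <- track_centroid(series, start, voxel_pitch = vp)
  expect_identical(nrow(track), 10L)
  err <- sqrt((track$y_um - ph$positions$y_um)^2 +
                (track$x_um - ph$positions$x_um)^2 +
                (track$z_um - ph$positions$z_um)^2)
  expect_lt(sqrt(mean(err^2)), max(vp))
  # a static sphere gives a constant path
  still <- rep(list(phantom_volume(ph, 1L)), 4L)
  ts <- track_centroid(still, start, voxel_pitch = vp)
  expect_equal(ts$y, rep(ts$y[1L], 4L), tolerance = 1e-12)
})

test_that("tracking error shrinks monotonically with SNR", {
  shape <- c(32L, 32L, 8L); vp <- c(1.5, 1.5, 2)
  ph <- make_flowing_cell(shape, vp, speed_um_per_s = 20,
                          frame_rate_hz = 20, n_frames = 6L,
                          cell_diameter_um = 5,
                          path_spec = list(radius_um = 5, pitch_um = 14))
  clean <- lapply(1:6, function(t) phantom_volume(ph, t))
  start <- c(ph$positions$y_um[1L] / 1.5 + 17,
             ph$positions$x_um[1L] / 1.5 + 17,
             ph$positions$z_um[1L] / 2 + 5)
  rms_at <- function(photons) {
    series <- lapply(clean, function(v) {
      vn <- v
      set.seed(17)
      vn[] <- stats::rpois(length(v), v * photons) / photons
      vn
    })
    track <- track_centroid(series, start, voxel_pitch = vp)
    err <- sqrt((track$y_um - ph$positions$y_um[track$frame])^2 +
                  (track$x_um - ph$positions$x_um[track$frame])^2 +
                  (track$z_um - ph$positions$z_um[track$frame])^2)
    sqrt(mean(err^2))
  }
  errs <- vapply(c(2, 50, 5000), rms_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})
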