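test_that("FWHM of a sampled Gaussian matches 2.3548 sigma", {
  n <- 41L
  x <- seq_len(n)
  make_vol <- function(sigma) {
    prof <- exp(-(x - 21)^2 / (2 * sigma^2))
    v <- array(0, c(n, n, 1L))
    v[, , 1L] <- outer(prof, prof)
    v
  }
  # 4.7096 um up to the linear-interpolation sampling error
  expect_equal(measure_fwhm(make_vol(2), "x", voxel_pitch = c(1, 1, 1)),
               2 * sqrt(2 * log(2)) * 2, tolerance = 0.012)
  for (sigma in c(1.5, 2.5, 4)) {
    got <- measure_fwhm(make_vol(sigma), "lateral",
                        voxel_pitch = c(1, 1, 1))
    expect_lt(abs(got - 2.3548 * sigma), 0.5)
  }
  # physical units scale with the pitch
  expect_equal(measure_fwhm(make_vol(2), "x", voxel_pitch = c(1, 2.5, 1)),
               2.5 * 2 * sqrt(2 * log(2)) * 2, tolerance = 0.02)
})

test_that("degenerate and asymmetric profiles are measured as specified", {
  v <- array(0, c(9L, 9L, 3L)); v[5L, 5L, 2L] <- 1
  expect_equal(measure_fwhm(v, "x", voxel_pitch = c(1, 1, 1)), 1)
  # hand-computed crossings of an asymmetric 7-sample profile:
  # (0, 2, 6, 10, 7, 3, 1), half-max 5 -> left 2.75, right 5.5, width 2.75
  expect_equal(siflfm:::fwhm_of_profile(c(0, 2, 6, 10, 7, 3, 1)), 2.75)
  # truncated peak errors out
  expect_error(siflfm:::fwhm_of_profile(c(5, 6, 8, 10)), "truncated")
})

test_that("locally weighted fits interpolate linear data exactly", {
  x <- seq(-20, 20, by = 2.5)
  y <- 2 * x + 1
  fit <- loess_fit(x, y, d = 10)
  expect_equal(fit$fit$y0, 2 * fit$fit$x0 + 1, tolerance = 1e-9)
  expect_equal(fit$fit$sigma, rep(0, nrow(fit$fit)), tolerance = 1e-7)
  expect_equal(fit$fit$ci_high - fit$fit$ci_low, rep(0, nrow(fit$fit)),
               tolerance = 1e-7)
  expect_error(loess_fit(rep(1, 5), 1:5), "degenerate")
})

test_that("locally weighted fits match the normal-equations oracle", {
  set.seed(31)
  x <- stats::runif(20, -30, 30)
  y <- 3 + 0.2 * x + 0.01 * x^2 + stats::rnorm(20, sd = 0.3)
  q <- seq(-25, 25, length.out = 11L)
  fit <- loess_fit(x, y, query_points = q, d = 10)
  for (i in seq_along(q)) {
    o <- wls_oracle(x, y, q[i], 10)
    expect_lt(abs(fit$fit$y0[i] - o$y0), 1e-10)
    expect_lt(abs(fit$fit$sigma[i] - o$sigma), 1e-10)
  }
  # CI is +-2 sigma around the fit
  expect_equal(fit$fit$ci_low, fit$fit$y0 - 2 * fit$fit$sigma)
  expect_equal(fit$fit$ci_high, fit$fit$y0 + 2 * fit$fit$sigma)
  # prediction refits at new points
  expect_equal(predict(fit, q[3L]), fit$fit$y0[3L])
})

bank <- tiny_bank()
np <- dim(bank$psfs)[1L]
nz <- dim(bank$psfs)[3L]

test_that("bead z-stacks yield PSFs matching the simulated bank", {
  # image one centred sub-resolution bead while stepping it through z
  frames <- lapply(seq_len(nz), function(iz) {
    vol <- array(0, c(np, np, nz))
    vol[siflfm:::centre_index(np), siflfm:::centre_index(np), iz] <- 1
    project_volume(vol, bank)
  })
  cal <- extract_psf_from_beads(frames, bank$view_centers, bank$z_grid,
                                pitch = 1.8,
                                crop_radius = (np - 1L) %/% 2L)
  expect_identical(cal$source, "calibrated")
  expect_identical(dim(cal$psfs)[3:4], dim(bank$psfs)[3:4])
  for (v in seq_len(dim(bank$psfs)[4L])) for (iz in seq_len(nz)) {
    a <- cal$psfs[, , iz, v]; b <- bank$psfs[, , iz, v]
    expect_gt(stats::cor(as.vector(a), as.vector(b)), 0.99)
  }
})

test_that("empty bead frames are rejected, naming view and depth", {
  frames <- lapply(seq_len(nz), function(iz) matrix(0, 3L * np, 3L * np))
  expect_error(extract_psf_from_beads(frames, bank$view_centers,
                                      bank$z_grid, pitch = 1.8,
                                      crop_radius = (np - 1L) %/% 2L),
               "view 1")
})

test_that("component ties break by intensity then by position", {
  img <- matrix(0, 20L, 20L)
  img[3:4, 3:4] <- 1        # same area, dimmer
  img[12:13, 12:13] <- 2    # same area, brighter
  comp <- siflfm:::largest_component(img, threshold_k = 5)
  expect_equal(comp$centroid, c(12.5, 12.5))
  img2 <- matrix(0, 20L, 20L)
  img2[3:4, 3:4] <- 1       # identical blobs: (row, col) order wins
  img2[12:13, 12:13] <- 1
  comp2 <- siflfm:::largest_component(img2, threshold_k = 5)
  expect_equal(comp2$centroid, c(3.5, 3.5))
})

test_that("resolution reports carry per-bead FWHMs and tight CIs for
           identical beads", {
  # synthetic volume of identical Gaussian spots at several depths
  n <- 25L; nzz <- 31L
  sig <- 1.8
  vol <- array(0, c(n, n, nzz))
  zpos <- c(6L, 11L, 16L, 21L, 26L)
  prof <- function(x0, s, n) exp(-((seq_len(n)) - x0)^2 / (2 * s^2))
  for (k in zpos) {
    spot <- outer(prof(13, sig, n), prof(13, sig, n))
    for (dz in -4:4)
      vol[, , k + dz] <- vol[, , k + dz] + spot * exp(-dz^2 / (2 * 1.5^2))
  }
  v <- flfm_volume(vol, z_grid = (seq_len(nzz) - 16) * 1.5, pitch = 1.2)
  beads <- cbind(13, 13, zpos)
  rep <- resolution_report(v, beads, d = 10)
  expect_identical(nrow(rep$table), 5L)
  expect_true(all(rep$table$fwhm_lateral_um > 0))
  # identical beads: residuals vanish, so the 95% band collapses
  width <- rep$lateral_fit$fit$ci_high - rep$lateral_fit$fit$ci_low
  expect_lt(max(width), 1e-6)
  expect_error(resolution_report(v, beads[1:3, ], d = 10), "at least 5")
})
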