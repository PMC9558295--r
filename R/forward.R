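# Linear forward camera model and its adjoint; simulated acquisition.

#' Reconstruction volume container
#'
#' @param data non-negative 3D array indexed [y, x, z].
#' @param z_grid depths in um, one per z plane.
#' @param pitch lateral voxel pitch in um (isotropic in y/x).
#' @return An object of class \code{flfm_volume}.
#' @export
flfm_volume <- function(data, z_grid, pitch) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3L] == length(z_grid))
  if (any(data < 0)) stop("volume must be non-negative", call. = FALSE)
  structure(list(data = data, z_grid = z_grid,
                 voxel_pitch = c(y = pitch, x = pitch,
                                 z = if (length(z_grid) > 1L)
                                       diff(z_grid)[1L] else NA_real_)),
            class = "flfm_volume")
}

#' @export
print.flfm_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("FLFM volume: %d x %d x %d voxels @ (%.3g, %.3g, %.3g) um, total %.4g\n",
              d[1L], d[2L], d[3L], x$voxel_pitch[1L], x$voxel_pitch[2L],
              x$voxel_pitch[3L], sum(x$data)))
  if (!is.null(x$loglik))
    cat(sprintf("  RL iterations: %d, final Poisson log-likelihood %.6g\n",
                length(x$loglik), x$loglik[length(x$loglik)]))
  invisible(x)
}

#' Maximum-intensity-projection display of a volume
#' @param x an \code{flfm_volume}.
#' @param ... passed to [graphics::image()].
#' @export
plot.flfm_volume <- function(x, ...) {
  mip <- apply(x$data, c(1L, 2L), max)
  graphics::image(t(mip)[, rev(seq_len(nrow(mip)))], asp = 1,
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  main = "MIP over z", ...)
  invisible(x)
}

# --- internal operator machinery ------------------------------------------

#' Precompute zero-padded OTFs for every (view, z) pair of a bank
#' @noRd
make_otf_stack <- function(bank) {
  d <- dim(bank$psfs)
  ny <- d[1L]; nx <- d[2L]; nz <- d[3L]; nv <- d[4L]
  ly <- stats::nextn(2L * ny - 1L)
  lx <- stats::nextn(2L * nx - 1L)
  otf <- vector("list", nv)
  for (v in seq_len(nv)) {
    o <- array(0i, c(ly, lx, nz))
    for (iz in seq_len(nz))
      o[, , iz] <- fft2(pad_to(bank$psfs[, , iz, v], ly, lx))
    otf[[v]] <- o
  }
  list(otf = otf, ny = ny, nx = nx, nz = nz, nv = nv, ly = ly, lx = lx,
       cy = centre_index(ny), cx = centre_index(nx))
}

#' Forward map: volume (optionally illumination-weighted) -> per-view images
#' @noRd
forward_views <- function(vol, ot) {
  vf <- array(0i, c(ot$ly, ot$lx, ot$nz))
  for (iz in seq_len(ot$nz))
    vf[, , iz] <- fft2(pad_to(vol[, , iz], ot$ly, ot$lx))
  out <- array(0, c(ot$ny, ot$nx, ot$nv))
  rows <- ot$cy:(ot$cy + ot$ny - 1L)
  cols <- ot$cx:(ot$cx + ot$nx - 1L)
  for (v in seq_len(ot$nv)) {
    acc <- matrix(0i, ot$ly, ot$lx)
    o <- ot$otf[[v]]
    for (iz in seq_len(ot$nz)) acc <- acc + o[, , iz] * vf[, , iz]
    out[, , v] <- Re(ifft2(acc))[rows, cols]
  }
  out
}

#' Exact adjoint of [forward_views()]: per-view images -> volume
#' @noRd
adjoint_views <- function(views, ot) {
  rows <- ot$cy:(ot$cy + ot$ny - 1L)
  cols <- ot$cx:(ot$cx + ot$nx - 1L)
  yf <- vector("list", ot$nv)
  for (v in seq_len(ot$nv)) {
    emb <- matrix(0, ot$ly, ot$lx)
    emb[rows, cols] <- views[, , v]
    yf[[v]] <- fft2(emb)
  }
  out <- array(0, c(ot$ny, ot$nx, ot$nz))
  for (iz in seq_len(ot$nz)) {
    acc <- matrix(0i, ot$ly, ot$lx)
    for (v in seq_len(ot$nv)) acc <- acc + Conj(ot$otf[[v]][, , iz]) * yf[[v]]
    out[, , iz] <- Re(ifft2(acc))[seq_len(ot$ny), seq_len(ot$nx)]
  }
  out
}

#' Weight a volume by the illumination pattern at one phase
#' @noRd
illuminate_volume <- function(vol, z_grid, pitch, pattern, phase_index) {
  if (is.null(pattern)) return(vol)
  out <- vol
  for (iz in seq_along(z_grid)) {
    w <- pattern_image(pattern, dim(vol)[1:2], pitch,
                       phase_index = phase_index, z = z_grid[iz])
    out[, , iz] <- vol[, , iz] * w
  }
  out
}

#' Stamp per-view sub-images onto a camera frame
#'
#' Sub-images are placed with their centre pixel at each (integer) view
#' centre. Overlapping placements raise an error.
#'
#' @param sub_images array [y, x, view].
#' @param centers n x 2 matrix of integer (y, x) view centres.
#' @param frame_shape optional (ny, nx) of the output frame; default just
#'   contains all sub-images.
#' @return The assembled frame matrix.
#' @export
stamp_views <- function(sub_images, centers, frame_shape = NULL) {
  d <- dim(sub_images)
  ny <- d[1L]; nx <- d[2L]; nv <- d[3L]
  if (any(abs(centers - round(centers)) > 1e-9))
    stop("view centres must be integer pixels for stamping", call. = FALSE)
  centers <- round(centers)
  oy <- centers[, 1L] - centre_index(ny) + 1L
  ox <- centers[, 2L] - centre_index(nx) + 1L
  if (any(oy < 1L) || any(ox < 1L))
    stop("sub-image placement falls off the frame", call. = FALSE)
  fs <- frame_shape %||% c(max(oy) + ny - 1L, max(ox) + nx - 1L)
  cover <- matrix(0L, fs[1L], fs[2L])
  frame <- matrix(0, fs[1L], fs[2L])
  for (v in seq_len(nv)) {
    ry <- oy[v]:(oy[v] + ny - 1L); rx <- ox[v]:(ox[v] + nx - 1L)
    if (max(ry) > fs[1L] || max(rx) > fs[2L])
      stop("sub-image placement falls off the frame", call. = FALSE)
    cover[ry, rx] <- cover[ry, rx] + 1L
    frame[ry, rx] <- frame[ry, rx] + sub_images[, , v]
  }
  if (any(cover > 1L))
    stop("sub-images overlap on the sensor", call. = FALSE)
  frame
}

#' Project a volume through the optical system onto the camera
#'
#' The forward model of the instrument: each z plane is weighted by the
#' structured-illumination pattern (if any), convolved with every view's PSF
#' at that depth, summed over depth, and the per-view images are stamped at
#' the bank's view centres.
#'
#' @param volume an \code{flfm_volume} or 3D array [y, x, z] whose z extent
#'   matches the bank's z grid.
#' @param bank a \code{psf_bank}.
#' @param pattern an \code{si_pattern}, or \code{NULL} for uniform
#'   illumination.
#' @param phase_index integer phase index k (phase advances by 2 pi / 3 per
#'   unit).
#' @return Camera frame matrix.
#' @export
project_volume <- function(volume, bank, pattern = NULL, phase_index = 0) {
  vol <- if (inherits(volume, "flfm_volume")) volume$data else volume
  stopifnot(inherits(bank, "psf_bank"))
  if (dim(vol)[3L] != length(bank$z_grid))
    stop("volume z extent does not match the PSF bank z grid", call. = FALSE)
  if (any(dim(vol)[1:2] != dim(bank$psfs)[1:2]))
    stop("volume lateral shape must match the PSF grid", call. = FALSE)
  ot <- make_otf_stack(bank)
  w <- illuminate_volume(vol, bank$z_grid, bank$pitch, pattern, phase_index)
  stamp_views(forward_views(w, ot), bank$view_centers)
}

#' Adjoint of [project_volume()] under uniform illumination
#'
#' Segments the frame at the bank's view centres and applies the transpose
#' of the per-view convolution model; this is the back-projection used
#' inside Richardson-Lucy deconvolution.
#'
#' @inheritParams project_volume
#' @param frame camera frame matrix.
#' @return 3D array [y, x, z].
#' @export
back_project <- function(frame, bank) {
  stopifnot(inherits(bank, "psf_bank"))
  d <- dim(bank$psfs)
  r <- (d[1L] - centre_index(d[1L]))   # radius below; crops are d1 x d2
  views <- array(0, c(d[1L], d[2L], d[4L]))
  for (v in seq_len(d[4L])) {
    cy <- round(bank$view_centers[v, 1L]); cx <- round(bank$view_centers[v, 2L])
    oy <- cy - centre_index(d[1L]) + 1L; ox <- cx - centre_index(d[2L]) + 1L
    views[, , v] <- frame[oy:(oy + d[1L] - 1L), ox:(ox + d[2L] - 1L)]
  }
  adjoint_views(views, make_otf_stack(bank))
}

#' Simulate a structured-illumination acquisition sequence
#'
#' Produces one camera frame per time step with the illumination phase
#' advancing by exactly 2 pi / 3 between consecutive frames (so frames k and
#' k + 3 share a phase). Optional Poisson shot noise (at a configured number
#' of photons per intensity unit) and zero-mean Gaussian read noise; both
#' are off by default. The returned object carries the phase and fringe
#' metadata the sectioning stage validates against.
#'
#' @param phantom a static \code{flfm_volume}/3D array, a list of such (one
#'   per frame), or a \code{phantom} object with time dynamics.
#' @param bank a \code{psf_bank}.
#' @param pattern an \code{si_pattern}.
#' @param n_frames number of frames (>= 3).
#' @param photon_scale photons per intensity unit for Poisson noise, or
#'   \code{NULL} for none.
#' @param read_sigma Gaussian read-noise sd in counts (0 = none).
#' @param seed RNG seed for the noise draws.
#' @return An object of class \code{raw_sequence}: \code{frames} (list of
#'   matrices), \code{phase_index}, \code{phase_offset}, \code{fringe_freq_px},
#'   \code{m0}, \code{contrast_model}, \code{view_centers}, \code{sub_shape},
#'   \code{pitch}, \code{seed}.
#' @export
simulate_si_sequence <- function(phantom, bank, pattern, n_frames,
                                 photon_scale = NULL, read_sigma = 0,
                                 seed = 0L) {
  stopifnot(inherits(bank, "psf_bank"), inherits(pattern, "si_pattern"))
  if (n_frames < 3) stop("need at least 3 frames (one phase period)",
                         call. = FALSE)
  if (!is.null(photon_scale) && photon_scale <= 0)
    stop("'photon_scale' must be positive", call. = FALSE)
  if (read_sigma < 0) stop("'read_sigma' must be >= 0", call. = FALSE)
  ot <- make_otf_stack(bank)
  get_vol <- function(t) {
    v <- if (inherits(phantom, "phantom")) phantom_volume(phantom, t)
         else if (is.list(phantom) && !inherits(phantom, "flfm_volume"))
           phantom[[t]]
         else phantom
    if (inherits(v, "flfm_volume")) v$data else v
  }
  frames <- vector("list", n_frames)
  with_seed(seed, {
    for (k in seq_len(n_frames)) {
      vol <- get_vol(k)
      w <- illuminate_volume(vol, bank$z_grid, bank$pitch, pattern, k - 1L)
      fr <- stamp_views(forward_views(w, ot), bank$view_centers)
      if (!is.null(photon_scale))
        fr[] <- stats::rpois(length(fr), pmax(fr, 0) * photon_scale) /
          photon_scale
      if (read_sigma > 0)
        fr[] <- fr + stats::rnorm(length(fr), sd = read_sigma)
      frames[[k]] <- fr
    }
  })
  structure(list(
    frames = frames,
    phase_index = seq_len(n_frames) - 1L,
    phase_offset = pattern$phase_offset,
    fringe_freq_px = pattern$fringe_frequency * bank$pitch,
    m0 = pattern$m0,
    contrast_model = pattern$contrast_model,
    view_centers = bank$view_centers,
    sub_shape = dim(bank$psfs)[1:2],
    pitch = bank$pitch,
    z_grid = bank$z_grid,
    seed = seed
  ), class = "raw_sequence")
}

#' @export
print.raw_sequence <- function(x, ...) {
  cat(sprintf("SI raw sequence: %d frames %dx%d, phases k = %s..., m0 = %.2f (%s)\n",
              length(x$frames), nrow(x$frames[[1L]]), ncol(x$frames[[1L]]),
              paste(utils::head(x$phase_index, 4L), collapse = ","),
              x$m0, x$contrast_model))
  invisible(x)
}
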