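# Scalar-diffraction PSF synthesis and illumination patterns.

#' Synthesize a per-view PSF bank
#'
#' Scalar Fourier-optics model of one microlens view: the view's circular
#' sub-aperture is cut out of the objective pupil at its layout offset, a
#' defocus phase is applied for each depth, and the intensity PSF is the
#' squared magnitude of the Fourier transform of the pupil field. Because
#' the defocus phase is evaluated on the full pupil coordinate (not the
#' sub-aperture centre), off-centre views acquire the depth-proportional
#' lateral shift (parallax) that multi-view 3D reconstruction relies on:
#' the centroid of view v at depth z sits at approximately
#' \code{z * pupil_offset_na[v]} in object space.
#'
#' PSFs are normalized jointly per depth so the whole-system PSF integrates
#' to one: \code{sum over views and pixels of psf[, , z, ] == 1} for every z
#' (photon-conservation convention).
#'
#' @param config an \code{flfm_config}.
#' @param derived matching \code{flfm_optics}.
#' @param layout matching \code{flfm_layout}.
#' @param grid_shape integer pair (ny, nx): lateral PSF/sub-image grid.
#' @param z_grid depths in um (default \code{seq(-z_range/2, z_range/2,
#'   z_step)}); z = 0 is the native object plane.
#' @param pitch object-space pixel pitch in um (default
#'   \code{derived$sample_pixel_pitch}).
#' @param defocus \code{"exact"} uses the full scalar propagation phase
#'   \code{(2 pi z / lambda) sqrt(n^2 - |u|^2)} (u the pupil coordinate in
#'   NA units); \code{"quadratic"} its paraxial expansion.
#' @param n_medium immersion refractive index (default 1.33, water).
#' @param footprint_tol maximum tolerated fraction of PSF energy in the
#'   two-pixel border frame before the grid is declared too small.
#' @return An object of class \code{psf_bank} with elements \code{psfs}
#'   (4D array [y, x, z, view]), \code{view_centers} (mosaic sensor centres,
#'   see Details), \code{pupil_offsets_na}, \code{z_grid}, \code{pitch},
#'   \code{source = "simulated"}.
#' @details Simulated banks carry a compact "mosaic" sensor geometry: the
#'   views are tiled on a near-square grid of non-overlapping sub-images of
#'   size \code{grid_shape}, which keeps simulated frames small. The
#'   physical sub-image centres of the full-scale instrument remain
#'   available in the layout (\code{sensor_centers_px}).
#' @export
synthesize_psf_bank <- function(config, derived, layout, grid_shape,
                                z_grid = NULL, pitch = NULL,
                                defocus = c("exact", "quadratic"),
                                n_medium = 1.33, footprint_tol = 0.01) {
  stopifnot(inherits(config, "flfm_config"), inherits(derived, "flfm_optics"),
            inherits(layout, "flfm_layout"))
  defocus <- match.arg(defocus)
  ny <- as.integer(grid_shape[1L]); nx <- as.integer(grid_shape[2L])
  pitch <- pitch %||% derived$sample_pixel_pitch
  z_grid <- z_grid %||% seq(-config$z_range / 2, config$z_range / 2,
                            by = config$z_step)
  lam <- config$emission_wavelength / 1000   # um
  nv <- layout$n_views
  nz <- length(z_grid)

  if (max(sqrt(rowSums(layout$pupil_offsets_na^2))) + layout$na_view >
        n_medium)
    stop("pupil extends beyond the immersion index: invalid geometry",
         call. = FALSE)
  fy <- fft_freq(ny, d = pitch)              # cycles / um
  fx <- fft_freq(nx, d = pitch)
  # pupil coordinate (NA units) relative to the view centre; the aperture
  # is representable on this grid for any offset, while the defocus phase
  # below is evaluated at the absolute coordinate c + u', whose tilt
  # component produces the depth-proportional parallax shift.
  upy <- matrix(lam * fy, ny, nx)
  upx <- matrix(lam * fx, ny, nx, byrow = TRUE)
  if (lam * min(1 / (2 * pitch)) < layout$na_view)
    stop("pixel pitch too coarse to sample the per-view aperture",
         call. = FALSE)

  psfs <- array(0, c(ny, nx, nz, nv))
  for (v in seq_len(nv)) {
    off <- layout$pupil_offsets_na[v, ]
    mask <- upy^2 + upx^2 <= layout$na_view^2
    uy <- upy + off[1L]
    ux <- upx + off[2L]
    u2 <- uy^2 + ux^2
    uz <- sqrt(pmax(0, n_medium^2 - u2))
    for (iz in seq_len(nz)) {
      z <- z_grid[iz]
      phase <- if (defocus == "exact") 2 * pi * z / lam * uz
               else -pi * z / (lam * n_medium) * u2   # up to a piston term
      field <- mask * exp(1i * phase)
      psfs[, , iz, v] <- fft_shift2(Mod(ifft2(field))^2)
    }
  }
  # grid-size check: energy trapped in the border frame must be negligible
  border <- rbind(
    cbind(rep(1:2, each = nx), rep(seq_len(nx), 2L)),
    cbind(rep((ny - 1L):ny, each = nx), rep(seq_len(nx), 2L)),
    cbind(rep(seq_len(ny), 2L), rep(1:2, each = ny)),
    cbind(rep(seq_len(ny), 2L), rep((nx - 1L):nx, each = ny)))
  for (v in seq_len(nv)) for (iz in seq_len(nz)) {
    pl <- psfs[, , iz, v]
    fr <- sum(pl[border]) / sum(pl)
    if (fr > footprint_tol) {
      shift_px <- max(abs(z_grid)) *
        max(sqrt(rowSums(layout$pupil_offsets_na^2))) / pitch
      stop(sprintf(paste0("PSF grid %dx%d too small: %.2g of view %d energy ",
                          "at z = %.3g um sits on the border; need roughly ",
                          ">= %d px per side"),
                   ny, nx, fr, v, z_grid[iz],
                   2L * ceiling(shift_px + 8)), call. = FALSE)
    }
  }
  for (iz in seq_len(nz)) {
    tot <- sum(psfs[, , iz, ])
    psfs[, , iz, ] <- psfs[, , iz, ] / tot
  }

  ntile <- ceiling(sqrt(nv))
  centers <- t(vapply(seq_len(nv), function(v) {
    r <- (v - 1L) %/% ntile
    c <- (v - 1L) %% ntile
    c(r * ny + centre_index(ny), c * nx + centre_index(nx))
  }, numeric(2)))
  colnames(centers) <- c("y", "x")

  structure(list(
    psfs = psfs,
    view_centers = centers,
    pupil_offsets_na = layout$pupil_offsets_na,
    z_grid = z_grid,
    pitch = pitch,
    source = "simulated"
  ), class = "psf_bank")
}

#' @export
print.psf_bank <- function(x, ...) {
  d <- dim(x$psfs)
  cat(sprintf("PSF bank (%s): %d views, %d z-planes (%.3g to %.3g um), %dx%d px @ %.3g um\n",
              x$source, d[4L], d[3L], min(x$z_grid), max(x$z_grid),
              d[1L], d[2L], x$pitch))
  invisible(x)
}

#' Sinusoidal structured-illumination pattern
#'
#' Describes the projected fringe pattern \code{1 + m(z) sin(2 pi f x + phi +
#' k 2 pi / 3)}: non-negative, mean one, with fringes along the x axis. The
#' unmodulated part of the in-focus excitation is thereby carried in the DC
#' term alongside the out-of-focus light, so the three-phase demodulation
#' recovers exactly the modulated in-focus amplitude.
#'
#' Two contrast models are available for the modulation depth \code{m(z)}:
#' \describe{
#'   \item{\code{eq5_ideal}}{\code{m(0) = m0}, zero at any other depth: only
#'     light in the native object plane is modulated.}
#'   \item{\code{gaussian_defocus}}{\code{m(z) = m0 exp(-(z/z_c)^2)} with
#'     \code{z_c = fringe_period_sample / (2 NA_illumination)}: fringe
#'     contrast decays with defocus as the projected grid blurs.}
#' }
#'
#' @param derived an \code{flfm_optics} (supplies the fringe period at the
#'   sample); alternatively pass \code{fringe_period_um} directly.
#' @param m0 base modulation depth in (0, 1].
#' @param phase_offset global phase phi, radians.
#' @param contrast_model \code{"eq5_ideal"} or \code{"gaussian_defocus"}.
#' @param na_illumination illumination NA for the defocus model (default:
#'   supply via \code{attr}, or the objective NA when built from a config).
#' @param fringe_period_um fringe period at the sample, um.
#' @return An object of class \code{si_pattern}.
#' @export
illumination_pattern <- function(derived = NULL, m0 = 1, phase_offset = 0,
                                 contrast_model = c("eq5_ideal",
                                                    "gaussian_defocus"),
                                 na_illumination = 1.05,
                                 fringe_period_um = NULL) {
  contrast_model <- match.arg(contrast_model)
  if (is.null(fringe_period_um)) {
    stopifnot(inherits(derived, "flfm_optics"))
    fringe_period_um <- derived$fringe_period_sample
  }
  if (m0 <= 0 || m0 > 1)
    stop("'m0' must lie in (0, 1] so the pattern stays non-negative",
         call. = FALSE)
  structure(list(
    fringe_frequency = 1 / fringe_period_um,   # cycles / um
    fringe_period_um = fringe_period_um,
    phase_offset = phase_offset,
    m0 = m0,
    contrast_model = contrast_model,
    na_illumination = na_illumination,
    z_c = fringe_period_um / (2 * na_illumination)
  ), class = "si_pattern")
}

#' Modulation depth m(z) of the illumination fringes
#'
#' @param z depth(s) in um (0 = native object plane).
#' @param pattern an \code{si_pattern}.
#' @return m(z) in [0, 1], same length as \code{z}.
#' @export
modulation_depth <- function(z, pattern) {
  stopifnot(inherits(pattern, "si_pattern"))
  switch(pattern$contrast_model,
    eq5_ideal = ifelse(z == 0, pattern$m0, 0),
    gaussian_defocus = pattern$m0 * exp(-(z / pattern$z_c)^2))
}

#' Render the illumination pattern on a pixel grid at one depth
#'
#' @param pattern an \code{si_pattern}.
#' @param shape integer pair (ny, nx).
#' @param pitch pixel pitch, um.
#' @param phase_index integer k; the rendered phase is
#'   \code{phase_offset + k * 2 pi / 3}.
#' @param z depth in um (controls the modulation depth).
#' @return ny x nx matrix, everywhere >= 0, mean ~ 1.
#' @export
pattern_image <- function(pattern, shape, pitch, phase_index = 0, z = 0) {
  stopifnot(inherits(pattern, "si_pattern"))
  ny <- as.integer(shape[1L]); nx <- as.integer(shape[2L])
  m <- modulation_depth(z, pattern)
  x_um <- (seq_len(nx) - centre_index(nx)) * pitch
  # reduce the phase index modulo the 3-phase period so the 2 pi
  # periodicity of the pattern is exact in floating point
  k <- as.integer(phase_index) %% 3L
  row <- 1 + m * sin(2 * pi * pattern$fringe_frequency * x_um +
                     pattern$phase_offset + k * 2 * pi / 3)
  matrix(row, ny, nx, byrow = TRUE)
}

#' Save a PSF bank as per-view TIFF stacks plus a JSON sidecar
#'
#' @param bank a \code{psf_bank}.
#' @param dir output directory (created if needed); writes
#'   \code{view_###.tif} (one page per z) and \code{bank.json}.
#' @export
save_psf_bank <- function(bank, dir) {
  stopifnot(inherits(bank, "psf_bank"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nv <- dim(bank$psfs)[4L]
  files <- sprintf("view_%03d.tif", seq_len(nv))
  for (v in seq_len(nv))
    write_stack(file.path(dir, files[v]), bank$psfs[, , , v])
  meta <- list(view_files = files,
               view_centers = unname(bank$view_centers),
               pupil_offsets_na = unname(bank$pupil_offsets_na),
               z_grid = bank$z_grid, pitch = bank$pitch,
               source = bank$source)
  write_sidecar(file.path(dir, "bank.json"), meta)
  invisible(dir)
}

#' Load a PSF bank saved by [save_psf_bank()]
#' @param dir directory containing \code{bank.json} and the view TIFFs.
#' @return A \code{psf_bank}.
#' @export
load_psf_bank <- function(dir) {
  meta <- read_sidecar(file.path(dir, "bank.json"))
  nv <- length(meta$view_files)
  first <- read_stack(file.path(dir, meta$view_files[[1L]]))
  psfs <- array(0, c(dim(first), nv))
  psfs[, , , 1L] <- first
  if (nv > 1L) for (v in 2:nv)
    psfs[, , , v] <- read_stack(file.path(dir, meta$view_files[[v]]))
  as_mat2 <- function(m) {
    if (is.matrix(m)) m else matrix(unlist(m), ncol = 2L, byrow = TRUE)
  }
  vc <- as_mat2(meta$view_centers)
  colnames(vc) <- c("y", "x")
  structure(list(
    psfs = psfs,
    view_centers = vc,
    pupil_offsets_na = as_mat2(meta$pupil_offsets_na),
    z_grid = as.numeric(unlist(meta$z_grid)),
    pitch = meta$pitch,
    source = meta$source
  ), class = "psf_bank")
}
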