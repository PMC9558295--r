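# Optical system model: configuration, derived parameters, microlens layout.

#' Optical system configuration
#'
#' Bundles the declared hardware values of a structured-illumination Fourier
#' light-field microscope: detection-path focal lengths, objective NA,
#' microlens array (MLA) geometry, wavelengths, camera pixel pitch and the
#' geometry of the digital micromirror device (DMD) that projects the
#' sinusoidal illumination fringes.
#'
#' Units follow optical-bench convention: focal lengths and the microlens
#' pitch in mm, wavelengths in nm, pixel pitches in um.
#' \code{illum_relay_magnification} is the single DMD-to-sample scale factor
#' (the product of the relay stages including the objective), so
#' \code{dmd_pixel_pitch * illum_relay_magnification} is the size of one DMD
#' pixel projected into object space.
#'
#' @param f_objective objective focal length, mm.
#' @param na_objective objective numerical aperture, in (0, 1.5].
#' @param f_tube tube-lens focal length, mm.
#' @param f_fourier Fourier-lens focal length, mm.
#' @param f_mla microlens focal length, mm.
#' @param d_mla microlens pitch, mm.
#' @param emission_wavelength emission wavelength, nm.
#' @param excitation_wavelength excitation wavelength, nm.
#' @param camera_pixel_pitch camera pixel pitch, um.
#' @param dmd_pixels DMD resolution, integer pair (width, height).
#' @param dmd_pixel_pitch DMD micromirror pitch, um.
#' @param illum_relay_magnification DMD-to-sample demagnification.
#' @param fringe_period_dmd illumination fringe period in DMD pixels (>= 2).
#' @param n_views_requested number of views to keep in the microlens layout.
#' @param z_range axial reconstruction range, um (centred on the native
#'   object plane).
#' @param z_step axial sampling step, um; \code{z_range} must be an integer
#'   multiple of it.
#' @return An object of class \code{flfm_config}.
#' @seealso [derive_system_parameters()], [generate_view_layout()],
#'   [default_optical_config()]
#' @export
optical_config <- function(f_objective, na_objective, f_tube, f_fourier,
                           f_mla, d_mla, emission_wavelength,
                           excitation_wavelength, camera_pixel_pitch,
                           dmd_pixels = c(1920L, 1080L),
                           dmd_pixel_pitch = 10.8,
                           illum_relay_magnification = 0.072,
                           fringe_period_dmd = 90L,
                           n_views_requested = NULL,
                           z_range = 90, z_step = 1.5) {
  for (nm in c("f_objective", "f_tube", "f_fourier", "f_mla", "d_mla",
               "emission_wavelength", "excitation_wavelength",
               "camera_pixel_pitch", "dmd_pixel_pitch",
               "illum_relay_magnification", "z_range", "z_step"))
    stopifnot_scalar_pos(get(nm), nm)
  if (na_objective <= 0 || na_objective > 1.5)
    stop("'na_objective' must lie in (0, 1.5]", call. = FALSE)
  if (fringe_period_dmd < 2)
    stop("'fringe_period_dmd' must be >= 2 DMD pixels", call. = FALSE)
  if (length(dmd_pixels) != 2L || any(dmd_pixels < 1))
    stop("'dmd_pixels' must be a positive integer pair", call. = FALSE)
  nz <- z_range / z_step
  if (abs(nz - round(nz)) > 1e-9)
    stop("'z_range' must be an integer multiple of 'z_step'", call. = FALSE)
  structure(list(
    f_objective = f_objective, na_objective = na_objective,
    f_tube = f_tube, f_fourier = f_fourier, f_mla = f_mla, d_mla = d_mla,
    emission_wavelength = emission_wavelength,
    excitation_wavelength = excitation_wavelength,
    camera_pixel_pitch = camera_pixel_pitch,
    dmd_pixels = as.integer(dmd_pixels),
    dmd_pixel_pitch = dmd_pixel_pitch,
    illum_relay_magnification = illum_relay_magnification,
    fringe_period_dmd = as.integer(fringe_period_dmd),
    n_views_requested = if (is.null(n_views_requested)) NULL
                        else as.integer(n_views_requested),
    z_range = z_range, z_step = z_step
  ), class = "flfm_config")
}

#' Reference instrument configuration
#'
#' The configuration shipped with the package (also available as the YAML
#' file \code{system_defaults.yaml} under \code{inst/extdata}): a 7.2 mm /
#' 1.05 NA water-immersion objective, 200 mm tube lens, 300 mm Fourier lens,
#' 3 mm-pitch f = 38.24 mm MLA, 470/525 nm excitation/emission, a
#' 1920 x 1080 DMD with a 90-pixel fringe period, and 31 views.
#'
#' @return An \code{flfm_config}.
#' @export
default_optical_config <- function() {
  path <- system.file("extdata", "system_defaults.yaml", package = "siflfm",
                      mustWork = TRUE)
  read_optical_config(path)
}

#' Read an optical configuration from a flat YAML file
#' @param path YAML file with one key per [optical_config()] argument.
#' @return An \code{flfm_config}.
#' @export
read_optical_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  do.call(optical_config, vals)
}

#' Write an optical configuration to YAML
#' @param config an \code{flfm_config}.
#' @param path output path.
#' @export
write_optical_config <- function(config, path) {
  stopifnot(inherits(config, "flfm_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Derive system parameters from an optical configuration
#'
#' Computes the quantities the configuration implies: intermediate
#' magnification \code{f_tube/f_objective}, total magnification after the
#' Fourier-lens/MLA stage, the per-view NA
#' \code{d_mla * f_tube / (2 * f_objective * f_fourier)}, the diameter of the
#' objective pupil image at the MLA plane, the field of view (one sub-image
#' diameter referred to object space), the depth of field, the extent of the
#' DMD projected into object space, the illumination fringe period at the
#' sample, and the object-space camera pixel pitch.
#'
#' The depth-of-field entry is a geometric estimate
#' (\code{lambda/NA_view^2 + pitch/NA_view}); multi-view reconstruction
#' supports a usable axial range a few times larger, which is why
#' \code{z_range} is configured independently.
#'
#' @param config an \code{flfm_config}.
#' @return An object of class \code{flfm_optics} (a named list).
#' @examples
#' d <- derive_system_parameters(default_optical_config())
#' round(d$mag_intermediate, 2)  # 27.78
#' round(d$mag_total, 2)         # 3.54
#' round(d$na_view, 3)           # 0.139
#' @export
derive_system_parameters <- function(config) {
  stopifnot(inherits(config, "flfm_config"))
  mag_int <- config$f_tube / config$f_objective
  mag_tot <- mag_int * config$f_mla / config$f_fourier
  na_view <- config$d_mla * config$f_tube /
    (2 * config$f_objective * config$f_fourier)
  pupil_d <- 2 * config$na_objective * config$f_objective *
    config$f_fourier / config$f_tube
  if (config$d_mla >= pupil_d)
    stop(sprintf(paste0("microlens pitch (%.3g mm) is not smaller than the ",
                        "pupil image (%.3g mm): no multi-view geometry"),
                 config$d_mla, pupil_d), call. = FALSE)
  lam_um <- config$emission_wavelength / 1000
  pitch_sample <- config$camera_pixel_pitch / mag_tot
  dmd_scale <- config$dmd_pixel_pitch * config$illum_relay_magnification
  structure(list(
    mag_intermediate = mag_int,
    mag_total = mag_tot,
    na_view = na_view,
    pupil_image_diameter = pupil_d,
    fov_diameter = config$d_mla * 1000 / mag_tot,
    dof = lam_um / na_view^2 + pitch_sample / na_view,
    dmd_projected_extent = config$dmd_pixels * dmd_scale,
    fringe_period_sample = config$fringe_period_dmd * dmd_scale,
    sample_pixel_pitch = pitch_sample
  ), class = "flfm_optics")
}

#' @export
print.flfm_optics <- function(x, ...) {
  cat("Derived FLFM optics\n")
  cat(sprintf("  intermediate magnification : %.2fx\n", x$mag_intermediate))
  cat(sprintf("  total magnification        : %.2fx\n", x$mag_total))
  cat(sprintf("  per-view NA                : %.3f\n", x$na_view))
  cat(sprintf("  pupil image at MLA         : %.2f mm\n", x$pupil_image_diameter))
  cat(sprintf("  field of view              : %.0f um\n", x$fov_diameter))
  cat(sprintf("  DMD projected extent       : %.0f x %.0f um\n",
              x$dmd_projected_extent[1], x$dmd_projected_extent[2]))
  cat(sprintf("  fringe period at sample    : %.2f um\n", x$fringe_period_sample))
  cat(sprintf("  object-space pixel pitch   : %.3f um\n", x$sample_pixel_pitch))
  invisible(x)
}

#' Microlens / view layout inside the pupil image
#'
#' Packs microlens centres hexagonally so that every sub-aperture lies wholly
#' inside the image of the objective pupil at the MLA plane. The view count
#' is geometry-driven; when \code{config$n_views_requested} is smaller than
#' the packed count, the outermost lenses are dropped (largest pupil radius
#' first, ties broken by angle) until the requested count remains.
#'
#' @param derived an \code{flfm_optics} from [derive_system_parameters()].
#' @param config the matching \code{flfm_config}.
#' @return An object of class \code{flfm_layout}: \code{mla_centers_mm}
#'   (n x 2, (y, x) at the MLA plane), \code{pupil_offsets_na} (n x 2, view
#'   centre direction cosines), \code{sensor_centers_px} (n x 2, physical
#'   sub-image centres on the camera relative to the optical axis),
#'   \code{n_views}, \code{na_view}.
#' @export
generate_view_layout <- function(derived, config) {
  stopifnot(inherits(derived, "flfm_optics"), inherits(config, "flfm_config"))
  p <- config$d_mla
  R <- derived$pupil_image_diameter / 2
  if (R <= p / 2)
    stop("pupil image smaller than one microlens: no views possible",
         call. = FALSE)
  K <- ceiling(2 * R / p) + 1L
  ij <- expand.grid(i = -K:K, j = -K:K)
  cx <- ij$i * p + ij$j * p / 2
  cy <- ij$j * p * sqrt(3) / 2
  r <- sqrt(cx^2 + cy^2)
  keep <- r + p / 2 <= R + 1e-12
  cx <- cx[keep]; cy <- cy[keep]; r <- r[keep]
  ang <- atan2(cy, cx)
  ord <- order(round(r, 9), round(ang, 9))
  cx <- cx[ord]; cy <- cy[ord]; r <- r[ord]
  n <- length(cx)
  if (n < 3)
    stop(sprintf("only %d view(s) fit the pupil: multi-view parallax impossible", n),
         call. = FALSE)
  want <- config$n_views_requested
  if (!is.null(want)) {
    if (want > n)
      stop(sprintf("requested %d views but geometry supports only %d", want, n),
           call. = FALSE)
    cx <- cx[seq_len(want)]; cy <- cy[seq_len(want)]; r <- r[seq_len(want)]
    n <- want
  }
  centers_mm <- cbind(y = cy, x = cx)
  offsets_na <- centers_mm / R * config$na_objective
  sensor_px <- centers_mm * 1000 / config$camera_pixel_pitch
  structure(list(
    mla_centers_mm = centers_mm,
    pupil_offsets_na = offsets_na,
    sensor_centers_px = sensor_px,
    n_views = n,
    na_view = derived$na_view
  ), class = "flfm_layout")
}

#' @export
print.flfm_layout <- function(x, ...) {
  cat(sprintf("FLFM view layout: %d views, per-view NA %.3f\n",
              x$n_views, x$na_view))
  cat(sprintf("  pupil offsets span |u| <= %.3f\n",
              max(sqrt(rowSums(x$pupil_offsets_na^2)))))
  invisible(x)
}
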