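# Seeded 3D phantom generators: bead fields, firing neurons, a flowing
# blood cell, and smooth out-of-focus background. All generators are pure
# functions of (parameters, seed) and carry their ground truth.

#' Render a sphere into a voxel grid with sub-voxel edge handling
#'
#' Voxel values are the fraction of the voxel inside the sphere, estimated
#' on a regular sub-voxel sampling grid, so bead edges are rendered
#' smoothly even for diameters close to the voxel pitch.
#' @noRd
render_sphere <- function(shape, pitch, center_um, diameter_um,
                          supersample = 4L) {
  ny <- shape[1L]; nx <- shape[2L]; nz <- shape[3L]
  R <- diameter_um / 2
  out <- array(0, shape)
  if (diameter_um < min(pitch)) {
    warning("bead diameter below one voxel in every axis; rendered as a ",
            "single-voxel impulse", call. = FALSE)
    idx <- pmin(pmax(round(center_um / pitch +
                             c(centre_index(ny), centre_index(nx),
                               centre_index(nz))), 1L), shape)
    out[idx[1L], idx[2L], idx[3L]] <- 1
    return(out)
  }
  ctr <- c(centre_index(ny), centre_index(nx), centre_index(nz))
  lo <- pmax(floor(center_um / pitch + ctr - R / pitch - 1), 1)
  hi <- pmin(ceiling(center_um / pitch + ctr + R / pitch + 1), shape)
  ss <- supersample
  sub <- (seq_len(ss) - (ss + 1) / 2) / ss
  offs <- as.matrix(expand.grid(dy = sub, dx = sub, dz = sub))
  for (k in lo[3L]:hi[3L]) for (j in lo[2L]:hi[2L]) for (i in lo[1L]:hi[1L]) {
    p <- (c(i, j, k) - ctr) * pitch - center_um
    # quick accept/reject by voxel corner distance
    dmin <- sqrt(sum(pmax(abs(p) - pitch / 2, 0)^2))
    if (dmin > R) next
    dmax <- sqrt(sum((abs(p) + pitch / 2)^2))
    if (dmax <= R) { out[i, j, k] <- 1; next }
    q <- sweep(offs, 2L, pitch, `*`)
    d2 <- (q[, 1L] + p[1L])^2 + (q[, 2L] + p[2L])^2 + (q[, 3L] + p[3L])^2
    out[i, j, k] <- mean(d2 <= R^2)
  }
  out
}

#' One-dimensional Gaussian smoothing along each axis of a 3D array
#' @noRd
gauss_blur3 <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq.int(-r, r), sd = s); k <- k / sum(k)
    a <- apply(a, setdiff(1:3, ax), function(line) {
      n <- length(line)
      ext <- c(rev(line[seq_len(min(r, n))]), line,
               rev(line)[seq_len(min(r, n))])
      while (length(ext) < n + 2L * r) ext <- c(ext[1L], ext, ext[length(ext)])
      stats::filter(ext, k, sides = 2)[(r + 1L):(r + n)]
    })
    a <- aperm(a, order(c(ax, setdiff(1:3, ax))))
  }
  a
}

new_phantom <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom '%s': %s voxels @ (%s) um, seed %d\n", x$kind,
              paste(x$volume_shape, collapse = "x"),
              paste(signif(x$voxel_pitch, 3), collapse = ", "),
              x$seed))
  invisible(x)
}

#' Volume rendered by a phantom at one time point
#'
#' @param phantom a \code{phantom}.
#' @param t frame index (1-based); ignored for static phantoms.
#' @return 3D array [y, x, z].
#' @export
phantom_volume <- function(phantom, t = 1L) {
  stopifnot(inherits(phantom, "phantom"))
  switch(phantom$kind,
    beads = phantom$volume,
    background = phantom$volume,
    neurons = {
      tr <- phantom$traces
      t <- min(t, nrow(tr))
      vol <- array(0, phantom$volume_shape)
      for (n in seq_len(ncol(tr))) {
        sv <- phantom$soma_voxels[[n]]
        vol[sv$index] <- vol[sv$index] +
          sv$value * phantom$baseline * (1 + tr[t, n])
      }
      vol
    },
    flowing_cell = {
      pos <- phantom$positions
      t <- min(t, nrow(pos))
      render_sphere(phantom$volume_shape, phantom$voxel_pitch,
                    as.numeric(pos[t, c("y_um", "x_um", "z_um")]),
                    phantom$cell_diameter_um)
    },
    stop("unknown phantom kind: ", phantom$kind))
}

#' Random field of fluorescent beads
#'
#' Emulates a sparse dilution of sub-resolution fluorescent beads
#' (default diameter 1.1 um) in a 3D volume. Centres are uniform inside the
#' volume (a margin of one bead radius keeps beads whole) unless given
#' explicitly.
#'
#' @param n_beads number of beads (>= 1).
#' @param volume_shape integer triplet (ny, nx, nz).
#' @param voxel_pitch um triplet (y, x, z).
#' @param bead_diameter_um bead diameter, um.
#' @param brightness per-bead peak intensity (scalar or length n).
#' @param seed RNG seed.
#' @param centers_um optional n x 3 matrix of centres (y, x, z) in um
#'   relative to the volume centre, overriding random placement.
#' @param z_range_um optional depth interval (min, max) to confine random
#'   bead depths, e.g. \code{c(0, 0)} for an in-focus-only field.
#' @param min_separation_um optional minimum pairwise centre distance,
#'   drawn by rejection sampling (models a dilution sparse enough that
#'   beads are individually resolvable; errors when the volume cannot hold
#'   the requested count at that separation).
#' @return A \code{phantom} with elements \code{volume} and ground-truth
#'   \code{emitters} (data frame of centres, diameter, brightness).
#' @export
make_bead_field <- function(n_beads, volume_shape, voxel_pitch,
                            bead_diameter_um = 1.1, brightness = 1,
                            seed = 0L, centers_um = NULL,
                            z_range_um = NULL, min_separation_um = 0) {
  if (n_beads < 1) stop("'n_beads' must be >= 1", call. = FALSE)
  shape <- as.integer(volume_shape)
  half <- (shape - 1) / 2 * voxel_pitch
  R <- bead_diameter_um / 2
  centers_um <- centers_um %||% with_seed(seed, {
    zr <- z_range_um %||% c(-half[3L] + R, half[3L] - R)
    draw <- function() c(stats::runif(1, -half[1L] + R, half[1L] - R),
                         stats::runif(1, -half[2L] + R, half[2L] - R),
                         stats::runif(1, zr[1L], min(zr[2L], max(zr))))
    pts <- matrix(draw(), 1L)
    tries <- 0L
    while (nrow(pts) < n_beads) {
      p <- draw()
      if (min_separation_um <= 0 ||
          min(sqrt(rowSums(sweep(pts, 2L, p, `-`)^2))) >= min_separation_um)
        pts <- rbind(pts, p)
      else {
        tries <- tries + 1L
        if (tries > 10000L * n_beads)
          stop("cannot place beads at the requested minimum separation",
               call. = FALSE)
      }
    }
    pts
  })
  brightness <- rep_len(brightness, n_beads)
  vol <- array(0, shape)
  for (b in seq_len(n_beads))
    vol <- vol + brightness[b] *
      render_sphere(shape, voxel_pitch, centers_um[b, ], bead_diameter_um)
  new_phantom("beads", volume = vol, volume_shape = shape,
              voxel_pitch = voxel_pitch, seed = as.integer(seed),
              emitters = data.frame(y_um = centers_um[, 1L],
                                    x_um = centers_um[, 2L],
                                    z_um = centers_um[, 3L],
                                    diameter_um = bead_diameter_um,
                                    brightness = brightness))
}

#' Calcium-transient response kernel
#'
#' Linear rise over \code{rise_frames} frames followed by exponential decay
#' with time constant \code{decay_tau_s}; peak value 1 at the end of the
#' rise (for a one-frame rise, at the event frame itself).
#'
#' @param n_frames kernel length in frames.
#' @param frame_rate_hz volume rate.
#' @param rise_frames rise time in frames.
#' @param decay_tau_s decay time constant, s.
#' @return Numeric vector of length \code{n_frames}.
#' @export
calcium_kernel <- function(n_frames, frame_rate_hz, rise_frames = 1,
                           decay_tau_s = 1.6) {
  j <- seq_len(n_frames) - 1
  rise <- pmin(1, (j + 1) / rise_frames)
  decay <- exp(-pmax(0, j - (rise_frames - 1)) / (decay_tau_s * frame_rate_hz))
  rise * decay
}

#' Scene of soma-like neurons with calcium-transient dynamics
#'
#' Spherical somata (diameters uniform in \code{soma_diameter_range_um})
#' placed at random; each neuron fires a Poisson event train at
#' \code{firing_rate_hz}, and its dF/F trace is the superposition of
#' [calcium_kernel()] responses (amplitude \code{amplitude} per event) on a
#' constant baseline.
#'
#' @param n_neurons number of neurons.
#' @param volume_shape integer triplet (ny, nx, nz).
#' @param voxel_pitch um triplet.
#' @param soma_diameter_range_um diameter range, um.
#' @param firing_rate_hz mean event rate per neuron.
#' @param frame_rate_hz volume rate.
#' @param duration_frames number of frames (>= 1).
#' @param rise_frames,decay_tau_s kernel parameters, see [calcium_kernel()].
#' @param amplitude dF/F amplitude of a single event.
#' @param baseline baseline fluorescence per unit soma volume.
#' @param seed RNG seed.
#' @param event_times optional list (one integer vector of event frames per
#'   neuron) overriding the Poisson draw.
#' @return A \code{phantom}; ground truth in \code{emitters}, \code{events}
#'   and the dF/F matrix \code{traces} [frame, neuron].
#' @export
make_neuron_scene <- function(n_neurons, volume_shape, voxel_pitch,
                              soma_diameter_range_um = c(6, 12),
                              firing_rate_hz = 0.2, frame_rate_hz = 10,
                              duration_frames = 100L,
                              rise_frames = 1, decay_tau_s = 1.6,
                              amplitude = 1, baseline = 1, seed = 0L,
                              event_times = NULL) {
  if (duration_frames < 1) stop("'duration_frames' must be >= 1", call. = FALSE)
  shape <- as.integer(volume_shape)
  half <- (shape - 1) / 2 * voxel_pitch
  drawn <- with_seed(seed, {
    dia <- stats::runif(n_neurons, soma_diameter_range_um[1L],
                        soma_diameter_range_um[2L])
    pos <- cbind(stats::runif(n_neurons, -half[1L] + dia / 2, half[1L] - dia / 2),
                 stats::runif(n_neurons, -half[2L] + dia / 2, half[2L] - dia / 2),
                 stats::runif(n_neurons, -half[3L] + dia / 2, half[3L] - dia / 2))
    ev <- event_times %||% lapply(seq_len(n_neurons), function(n) {
      counts <- stats::rpois(duration_frames, firing_rate_hz / frame_rate_hz)
      rep(seq_len(duration_frames), counts)
    })
    list(dia = dia, pos = pos, ev = ev)
  })
  kern <- calcium_kernel(duration_frames, frame_rate_hz, rise_frames,
                         decay_tau_s)
  traces <- matrix(0, duration_frames, n_neurons)
  for (n in seq_len(n_neurons)) for (te in drawn$ev[[n]]) {
    j <- te:duration_frames
    traces[j, n] <- traces[j, n] + amplitude * kern[j - te + 1L]
  }
  soma_voxels <- lapply(seq_len(n_neurons), function(n) {
    s <- render_sphere(shape, voxel_pitch, drawn$pos[n, ], drawn$dia[n])
    idx <- which(s > 0)
    list(index = idx, value = s[idx])
  })
  new_phantom("neurons", volume_shape = shape, voxel_pitch = voxel_pitch,
              seed = as.integer(seed), baseline = baseline,
              frame_rate_hz = frame_rate_hz,
              emitters = data.frame(y_um = drawn$pos[, 1L],
                                    x_um = drawn$pos[, 2L],
                                    z_um = drawn$pos[, 3L],
                                    diameter_um = drawn$dia),
              events = drawn$ev, traces = traces,
              soma_voxels = soma_voxels)
}

#' A single cell flowing along a 3D path at constant speed
#'
#' Default path is a helix (constant-speed by construction); a straight
#' line is also available. Ground-truth positions are stored per frame.
#'
#' @param volume_shape integer triplet.
#' @param voxel_pitch um triplet.
#' @param speed_um_per_s flow speed.
#' @param frame_rate_hz sampling rate; higher rates sample the same path
#'   more densely.
#' @param n_frames number of frames.
#' @param cell_diameter_um cell diameter, um.
#' @param path \code{"helix"} or \code{"line"}.
#' @param path_spec list of path parameters: for \code{helix},
#'   \code{radius_um} and \code{pitch_um} (axial advance per turn, along x);
#'   for \code{line}, \code{start_um} and \code{direction}.
#' @param sub_image_extent_um optional lateral sub-image extent; a warning
#'   is raised when the per-frame displacement exceeds half of it
#'   (tracking aliasing).
#' @param seed RNG seed (kept for interface symmetry; the path itself is
#'   deterministic).
#' @return A \code{phantom}; ground truth in \code{positions} (data frame
#'   frame, t_s, y_um, x_um, z_um).
#' @export
make_flowing_cell <- function(volume_shape, voxel_pitch, speed_um_per_s,
                              frame_rate_hz, n_frames,
                              cell_diameter_um = 5,
                              path = c("helix", "line"), path_spec = NULL,
                              sub_image_extent_um = NULL, seed = 0L) {
  path <- match.arg(path)
  shape <- as.integer(volume_shape)
  half <- (shape - 1) / 2 * voxel_pitch
  t_s <- (seq_len(n_frames) - 1L) / frame_rate_hz
  s <- speed_um_per_s * t_s                    # arc length travelled
  if (path == "helix") {
    a <- (path_spec$radius_um %||% (0.4 * min(half[c(1L, 3L)])))
    b <- (path_spec$pitch_um %||% (0.8 * half[2L])) / (2 * pi)
    theta0 <- -s[length(s)] / (2 * sqrt(a^2 + b^2))
    theta <- theta0 + s / sqrt(a^2 + b^2)
    pos <- cbind(y_um = a * sin(theta), x_um = b * theta,
                 z_um = a * cos(theta))
  } else {
    start <- path_spec$start_um %||% c(0, -half[2L] * 0.8, 0)
    dirv <- path_spec$direction %||% c(0, 1, 0)
    dirv <- dirv / sqrt(sum(dirv^2))
    pos <- cbind(y_um = start[1L] + s * dirv[1L],
                 x_um = start[2L] + s * dirv[2L],
                 z_um = start[3L] + s * dirv[3L])
  }
  out_of_volume <- abs(pos) > matrix(half, n_frames, 3L, byrow = TRUE)
  if (any(out_of_volume))
    stop("path leaves the volume; shrink the path or speed", call. = FALSE)
  step_um <- speed_um_per_s / frame_rate_hz
  if (!is.null(sub_image_extent_um) && step_um > sub_image_extent_um / 2)
    warning(sprintf(paste0("per-frame displacement %.3g um exceeds half a ",
                           "sub-image (%.3g um): tracking may alias"),
                    step_um, sub_image_extent_um), call. = FALSE)
  new_phantom("flowing_cell", volume_shape = shape,
              voxel_pitch = voxel_pitch, seed = as.integer(seed),
              cell_diameter_um = cell_diameter_um,
              positions = data.frame(frame = seq_len(n_frames), t_s = t_s,
                                     y_um = pos[, 1L], x_um = pos[, 2L],
                                     z_um = pos[, 3L]))
}

#' Smooth out-of-focus background field
#'
#' A positive low-pass-filtered random field confined to planes beyond a
#' stated defocus (where the illumination fringes carry no contrast), scaled
#' so that its total intensity is \code{strength} times \code{signal_total}.
#' This emulates the strong unmodulated background that dominates raw
#' light-field frames of scattering tissue.
#'
#' @param volume_shape integer triplet (ny, nx, nz).
#' @param voxel_pitch um triplet.
#' @param strength target ratio (background total) / (in-focus signal
#'   total); 0 gives a zero field.
#' @param signal_total total intensity of the in-focus signal the ratio is
#'   referred to.
#' @param correlation_length_um Gaussian correlation length of the field.
#' @param z_exclude_um planes with |z| <= this stay empty (default: keep
#'   only the outermost third of the z range).
#' @param seed RNG seed.
#' @return A \code{phantom} with the field in \code{volume} and the realized
#'   ratio in \code{strength}.
#' @export
make_background <- function(volume_shape, voxel_pitch, strength,
                            signal_total = 1, correlation_length_um = 10,
                            z_exclude_um = NULL, seed = 0L) {
  if (strength < 0) stop("'strength' must be >= 0", call. = FALSE)
  shape <- as.integer(volume_shape)
  vol <- array(0, shape)
  z_um <- (seq_len(shape[3L]) - centre_index(shape[3L])) * voxel_pitch[3L]
  z_exclude_um <- z_exclude_um %||% (max(abs(z_um)) / 3)
  live <- abs(z_um) > z_exclude_um + 1e-12
  if (strength > 0) {
    if (!any(live))
      stop("no planes beyond 'z_exclude_um' to hold the background",
           call. = FALSE)
    raw <- with_seed(seed, array(stats::rnorm(prod(shape)), shape))
    sm <- gauss_blur3(raw, correlation_length_um / voxel_pitch)
    sm <- sm - min(sm)
    sm[, , !live] <- 0
    tot <- sum(sm)
    if (tot <= 0) sm[, , live] <- 1 else sm <- sm / tot
    vol <- sm * strength * signal_total
  }
  new_phantom("background", volume = vol, volume_shape = shape,
              voxel_pitch = voxel_pitch, seed = as.integer(seed),
              strength = strength, z_exclude_um = z_exclude_um)
}
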