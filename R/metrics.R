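# Evaluation metrics: signal-to-background ratio, dF/F traces, 3D tracking.

#' Spherical ROI with a background annulus
#'
#' @param center (y, x, z) voxel indices of the ROI centre.
#' @param roi_radius ROI sphere radius, voxels.
#' @param annulus_inner,annulus_outer background shell radii, voxels;
#'   \code{roi_radius < annulus_inner < annulus_outer}.
#' @return An object of class \code{roi_spec}.
#' @export
roi_spec <- function(center, roi_radius, annulus_inner, annulus_outer) {
  if (annulus_inner <= roi_radius)
    stop("'annulus_inner' must exceed 'roi_radius'", call. = FALSE)
  if (annulus_outer <= annulus_inner)
    stop("'annulus_outer' must exceed 'annulus_inner'", call. = FALSE)
  structure(list(center = as.numeric(center), roi_radius = roi_radius,
                 annulus_inner = annulus_inner,
                 annulus_outer = annulus_outer), class = "roi_spec")
}

roi_masks <- function(dims, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  if (any(roi$center < 1) || any(roi$center > dims))
    stop("ROI centre lies outside the volume", call. = FALSE)
  dy <- seq_len(dims[1L]) - roi$center[1L]
  dx <- seq_len(dims[2L]) - roi$center[2L]
  dz <- seq_len(dims[3L]) - roi$center[3L]
  d2 <- outer(outer(dy^2, dx^2, `+`), dz^2, `+`)
  list(roi = d2 <= roi$roi_radius^2,
       annulus = d2 > roi$annulus_inner^2 & d2 <= roi$annulus_outer^2)
}

#' Signal-to-background ratio of one ROI
#'
#' Operational definition: contrast of the ROI sphere over its local
#' background annulus,
#' \code{SBR = (mean(ROI) - mean(annulus)) / mean(annulus)}. Invariant
#' under global intensity scaling; zero when ROI and annulus match.
#'
#' @param volume an \code{flfm_volume} or 3D array.
#' @param roi an \code{roi_spec}.
#' @return SBR (scalar).
#' @export
compute_sbr <- function(volume, roi) {
  vol <- if (inherits(volume, "flfm_volume")) volume$data else volume
  m <- roi_masks(dim(vol), roi)
  bg <- mean(vol[m$annulus])
  if (!is.finite(bg) || bg <= 0)
    stop("background annulus mean is not positive: SBR undefined",
         call. = FALSE)
  (mean(vol[m$roi]) - bg) / bg
}

#' Median SBR comparison between sectioned and plain reconstructions
#'
#' Computes the per-ROI SBR in both volumes and the ratio of their medians
#' (lower-of-the-two-middles convention for even counts). This is the
#' quantity by which structured-illumination processing is judged against
#' plain uniform-illumination processing on the same scene.
#'
#' @param volume_si volume reconstructed from sectioned data.
#' @param volume_plain volume reconstructed from uniform data.
#' @param rois list of \code{roi_spec}s (matched between the two).
#' @return List: \code{median_si}, \code{median_plain},
#'   \code{improvement_factor}, and per-ROI \code{sbr_si},
#'   \code{sbr_plain}.
#' @export
sbr_statistics <- function(volume_si, volume_plain, rois) {
  if (length(rois) == 0L) stop("empty ROI set", call. = FALSE)
  s_si <- vapply(rois, function(r) compute_sbr(volume_si, r), numeric(1))
  s_pl <- vapply(rois, function(r) compute_sbr(volume_plain, r), numeric(1))
  m_si <- median_low(s_si)
  m_pl <- median_low(s_pl)
  list(median_si = m_si, median_plain = m_pl,
       improvement_factor = m_si / m_pl,
       sbr_si = s_si, sbr_plain = s_pl)
}

#' dF/F traces of ROIs over a volume time series
#'
#' For each ROI: \code{F(t)} is the ROI-sphere mean, the baseline \code{F0}
#' a low percentile of \code{F} (default the 10th), and the trace
#' \code{(F - F0) / F0}.
#'
#' @param volume_series list of volumes (>= 10 time points).
#' @param rois list of \code{roi_spec}s.
#' @param baseline_percentile baseline percentile in (0, 1).
#' @return Matrix [time, roi] of dF/F values, with the raw fluorescence in
#'   \code{attr(, "f_raw")} and baselines in \code{attr(, "f0")}.
#' @export
dff_traces <- function(volume_series, rois, baseline_percentile = 0.1) {
  if (length(volume_series) < 10L)
    stop("need at least 10 time points for a baseline estimate",
         call. = FALSE)
  get_data <- function(v) if (inherits(v, "flfm_volume")) v$data else v
  dims <- dim(get_data(volume_series[[1L]]))
  f <- vapply(volume_series, function(v) {
    vol <- get_data(v)
    vapply(rois, function(r) mean(vol[roi_masks(dims, r)$roi]), numeric(1))
  }, numeric(length(rois)))
  f <- t(matrix(f, nrow = length(rois)))   # [time, roi]
  f0 <- apply(f, 2L, stats::quantile, probs = baseline_percentile,
              names = FALSE)
  if (any(f0 <= 0))
    stop("baseline F0 <= 0: dF/F undefined", call. = FALSE)
  dff <- sweep(sweep(f, 2L, f0, `-`), 2L, f0, `/`)
  attr(dff, "f_raw") <- f
  attr(dff, "f0") <- f0
  dff
}

#' Track the 3D centroid of a moving object through a volume series
#'
#' Per frame: voxels above \code{threshold_fraction} of the frame maximum
#' are labelled into connected components; the component whose centroid is
#' nearest the previous position is kept, and its intensity-weighted
#' centroid becomes the new position. If no component lies within
#' \code{search_radius} the track is truncated with a warning.
#'
#' @param volume_series list of volumes.
#' @param start_position (y, x, z) voxel indices near the object in frame 1.
#' @param threshold_fraction fraction of the per-frame maximum (default
#'   0.5).
#' @param search_radius maximum allowed jump between frames, voxels
#'   (default: a quarter of the smallest volume dimension).
#' @param voxel_pitch um triplet for physical coordinates (default from
#'   the volumes).
#' @return Data frame: frame, y, x, z (voxels) and y_um, x_um, z_um
#'   (relative to the volume centre).
#' @export
track_centroid <- function(volume_series, start_position,
                           threshold_fraction = 0.5, search_radius = NULL,
                           voxel_pitch = NULL) {
  get_data <- function(v) if (inherits(v, "flfm_volume")) v$data else v
  first <- volume_series[[1L]]
  if (is.null(voxel_pitch))
    voxel_pitch <- if (inherits(first, "flfm_volume")) first$voxel_pitch
                   else c(1, 1, 1)
  dims <- dim(get_data(first))
  search_radius <- search_radius %||% max(3, min(dims) / 4)
  prev <- as.numeric(start_position)
  rows <- list()
  for (t in seq_along(volume_series)) {
    vol <- get_data(volume_series[[t]])
    thr <- threshold_fraction * max(vol)
    lab <- label_components_3d(vol >= thr)
    n <- max(lab)
    if (n == 0L) {
      warning(sprintf("object lost at frame %d: track truncated", t),
              call. = FALSE)
      break
    }
    cents <- t(vapply(seq_len(n), function(l)
      array_centroid(ifelse(lab == l, vol, 0)), numeric(3)))
    dist2 <- rowSums(sweep(cents, 2L, prev, `-`)^2)
    best <- which.min(dist2)
    if (sqrt(dist2[best]) > search_radius) {
      warning(sprintf("object lost at frame %d: track truncated", t),
              call. = FALSE)
      break
    }
    prev <- cents[best, ]
    rows[[t]] <- data.frame(frame = t, y = prev[1L], x = prev[2L],
                            z = prev[3L])
  }
  out <- do.call(rbind, rows)
  ctr <- vapply(seq_len(3L), function(k) centre_index(dims[k]), numeric(1))
  out$y_um <- (out$y - ctr[1L]) * voxel_pitch[1L]
  out$x_um <- (out$x - ctr[2L]) * voxel_pitch[2L]
  out$z_um <- (out$z - ctr[3L]) * voxel_pitch[3L]
  out
}
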