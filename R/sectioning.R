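# Three-phase optical sectioning, refined-SIM frequency fusion, and
# interleaved sliding-window reconstruction.

#' Bundle three phase-shifted frames
#'
#' @param i1,i2,i3 equal-shape non-negative matrices acquired at
#'   illumination phases phi, phi + 2 pi / 3, phi + 4 pi / 3.
#' @param phase_offset global phase phi, radians (metadata only; the
#'   demodulation is invariant to it).
#' @return An object of class \code{phase_triplet}.
#' @export
phase_triplet <- function(i1, i2, i3, phase_offset = 0) {
  if (!all(dim(i1) == dim(i2)) || !all(dim(i1) == dim(i3)))
    stop("phase images must share one shape", call. = FALSE)
  structure(list(i1 = i1, i2 = i2, i3 = i3, phase_offset = phase_offset),
            class = "phase_triplet")
}

as_triplet <- function(x) {
  if (inherits(x, "phase_triplet")) return(x)
  if (is.list(x) && length(x) == 3L) return(phase_triplet(x[[1]], x[[2]], x[[3]]))
  stop("expected a phase_triplet or a list of three images", call. = FALSE)
}

#' Three-phase optical sectioning (root-sum-square demodulation)
#'
#' Pixelwise demodulation of a triplet of frames under sinusoidal
#' illumination with phases 2 pi / 3 apart:
#' \deqn{I_{OS} = \sqrt{(I_1-I_2)^2 + (I_1-I_3)^2 + (I_2-I_3)^2}.}
#' Unmodulated (out-of-focus) light cancels in the pairwise differences, so
#' the result contains only the modulated in-focus amplitude. The raw
#' root-sum-square equals \code{(3/sqrt(2))} times the local modulated
#' amplitude; with \code{normalized = TRUE} (default) the output is scaled
#' by \code{sqrt(2)/3} so it equals the amplitude exactly, which keeps the
#' subsequent low-pass/high-pass fusion amplitude-consistent.
#'
#' @param triplet a \code{phase_triplet} (or list of three images).
#' @param normalized scale by \code{sqrt(2)/3} (see above).
#' @return Demodulated image (matrix, >= 0).
#' @export
optical_section_triplet <- function(triplet, normalized = TRUE) {
  tr <- as_triplet(triplet)
  out <- sqrt((tr$i1 - tr$i2)^2 + (tr$i1 - tr$i3)^2 + (tr$i2 - tr$i3)^2)
  if (normalized) out <- out * sqrt(2) / 3
  out
}

#' Uniform-illumination equivalent of a phase triplet
#'
#' Because the three phase patterns sum to a constant, the pixel mean of a
#' triplet is the frame that a uniform (conventional light-field) exposure
#' would have produced: out-of-focus light plus the unmodulated in-focus DC.
#'
#' @inheritParams optical_section_triplet
#' @return Mean image (matrix).
#' @export
uniform_from_triplet <- function(triplet) {
  tr <- as_triplet(triplet)
  (tr$i1 + tr$i2 + tr$i3) / 3
}

#' Complementary low-pass / high-pass transfer functions for RSIM fusion
#'
#' A single isotropic Gaussian transfer \code{G(f) = exp(-f^2 / (2 s^2))}
#' with \code{s = cutoff_fraction * f_fringe / 2}, so the low-pass has
#' fallen to \code{exp(-2)} at the cutoff and is below 1e-3 at the fringe
#' frequency itself. The high-pass is \code{1 - G}; the pair sums to one at
#' every frequency by construction.
#'
#' @param shape (ny, nx) of the (padded) image the transfer applies to.
#' @param fringe_freq_px fringe frequency in cycles/pixel.
#' @param cutoff_fraction cutoff as a fraction of the fringe frequency,
#'   in (0, 1).
#' @return List with matrices \code{lp} and \code{hp} in unshifted FFT
#'   layout.
#' @export
rsim_transfer <- function(shape, fringe_freq_px, cutoff_fraction = 0.5) {
  if (cutoff_fraction <= 0 || cutoff_fraction >= 1)
    stop("'cutoff_fraction' must lie in (0, 1)", call. = FALSE)
  f_c <- cutoff_fraction * fringe_freq_px
  if (f_c >= 0.5)
    stop("cutoff frequency reaches Nyquist; lower 'cutoff_fraction'",
         call. = FALSE)
  fy <- fft_freq(shape[1L]); fx <- fft_freq(shape[2L])
  f2 <- outer(fy^2, fx^2, `+`)
  s <- f_c / 2
  lp <- exp(-f2 / (2 * s^2))
  list(lp = lp, hp = 1 - lp)
}

#' Refined-SIM fusion of sectioned and uniform images
#'
#' The root-sum-square demodulation leaves residual artifacts at the fringe
#' frequency and amplifies high-frequency noise; the uniform image has
#' clean high frequencies but carries the out-of-focus haze at low
#' frequencies. Fusion takes the low-pass band of the sectioned image and
#' the complementary high-pass band of the uniform image:
#' \code{LP(I_OS) + HP(I_UI)}. Images are mirror-padded before filtering to
#' suppress boundary ringing; negative excursions are clipped to zero.
#'
#' @param i_os sectioned image from [optical_section_triplet()].
#' @param i_ui uniform image from [uniform_from_triplet()].
#' @param fringe_freq_px fringe frequency in cycles/pixel.
#' @param cutoff_fraction cutoff as a fraction of the fringe frequency.
#' @return Fused in-focus image (matrix, >= 0).
#' @export
rsim_fuse <- function(i_os, i_ui, fringe_freq_px, cutoff_fraction = 0.5) {
  if (!all(dim(i_os) == dim(i_ui)))
    stop("sectioned and uniform images must share one shape", call. = FALSE)
  ny <- nrow(i_os); nx <- ncol(i_os)
  r <- min(ny, nx)                       # full mirror margin
  pad_os <- mirror_pad(i_os, r)
  pad_ui <- mirror_pad(i_ui, r)
  tf <- rsim_transfer(dim(pad_os), fringe_freq_px, cutoff_fraction)
  fused <- Re(ifft2(fft2(pad_os) * tf$lp + fft2(pad_ui) * tf$hp))
  pmax(fused[(r + 1L):(r + ny), (r + 1L):(r + nx)], 0)
}

#' Sliding three-frame windows for interleaved reconstruction
#'
#' Any three consecutive frames of a 2 pi / 3 phase-stepped sequence form a
#' valid demodulation triplet, so n raw frames yield n - 2 sectioned frames
#' (3n - 2 from 3n) instead of one per period.
#'
#' @param n_raw_frames number of raw frames (>= 3).
#' @return Integer matrix with one row (i, i+1, i+2) per window, 1-based.
#' @export
interleaved_windows <- function(n_raw_frames) {
  if (n_raw_frames < 3)
    stop("need at least 3 raw frames for one demodulation window",
         call. = FALSE)
  i <- seq_len(n_raw_frames - 2L)
  cbind(i, i + 1L, i + 2L, deparse.level = 0)
}

#' Section a raw sequence with interleaved sliding windows
#'
#' Runs root-sum-square demodulation, uniform-image synthesis and RSIM
#' fusion on every window of three consecutive frames, yielding 3n - 2
#' sectioned frames from 3n raw frames. Phase metadata is validated: frames
#' must advance by exactly one phase step (2 pi / 3) each.
#'
#' When the sequence carries view geometry and \code{per_view = TRUE}
#' (default), the RSIM filtering runs on each segmented sub-image
#' separately (the pixelwise demodulation itself is identical either way).
#' When the simulated modulation depth \code{m0} is below one it is divided
#' out (\code{rescale_m0}), so fused amplitudes match the uniform image's
#' in-focus content.
#'
#' @param raw a \code{raw_sequence}, or a plain list of frames (then
#'   \code{fringe_freq_px} must be given).
#' @param normalized,cutoff_fraction see [optical_section_triplet()] and
#'   [rsim_fuse()].
#' @param rescale_m0 divide the sectioned image by the known modulation
#'   depth.
#' @param per_view filter per segmented view when geometry is available.
#' @param fuse set \code{FALSE} to skip RSIM fusion and return the plain
#'   demodulated images.
#' @param fringe_freq_px fringe frequency in cycles/pixel (overrides the
#'   sequence metadata).
#' @return List of \code{sectioned_frame} objects: \code{image},
#'   \code{window} (raw-frame indices), \code{timestamp} (centre index).
#' @export
section_sequence <- function(raw, normalized = TRUE, cutoff_fraction = 0.5,
                             rescale_m0 = TRUE, per_view = TRUE,
                             fuse = TRUE, fringe_freq_px = NULL) {
  if (inherits(raw, "raw_sequence")) {
    frames <- raw$frames
    ph <- raw$phase_index
    dph <- diff(ph)
    if (any(dph != 1L)) {
      bad <- which(dph != 1L)[1L]
      stop(sprintf(paste0("phase stepping is not uniform: frame %d -> %d ",
                          "advances %d phase step(s), expected 1"),
                   bad, bad + 1L, dph[bad]), call. = FALSE)
    }
    fringe_freq_px <- fringe_freq_px %||% raw$fringe_freq_px
    m0 <- if (rescale_m0) raw$m0 else 1
    geom <- if (per_view && !is.null(raw$view_centers))
      list(centers = raw$view_centers, sub_shape = raw$sub_shape) else NULL
  } else {
    frames <- raw
    m0 <- 1
    geom <- NULL
    if (fuse && is.null(fringe_freq_px))
      stop("'fringe_freq_px' is required when sectioning plain frames",
           call. = FALSE)
  }
  win <- interleaved_windows(length(frames))
  lapply(seq_len(nrow(win)), function(w) {
    idx <- win[w, ]
    tr <- phase_triplet(frames[[idx[1L]]], frames[[idx[2L]]],
                        frames[[idx[3L]]])
    os <- optical_section_triplet(tr, normalized = normalized) / m0
    img <- if (!fuse) os else {
      ui <- uniform_from_triplet(tr)
      if (is.null(geom)) rsim_fuse(os, ui, fringe_freq_px, cutoff_fraction)
      else apply_per_view(os, ui, geom, fringe_freq_px, cutoff_fraction)
    }
    structure(list(image = img, window = idx, timestamp = idx[2L]),
              class = "sectioned_frame")
  })
}

#' Fuse per segmented view and re-stamp into the frame
#' @noRd
apply_per_view <- function(os, ui, geom, fringe_freq_px, cutoff_fraction) {
  ny <- geom$sub_shape[1L]; nx <- geom$sub_shape[2L]
  out <- matrix(0, nrow(os), ncol(os))
  for (v in seq_len(nrow(geom$centers))) {
    cy <- round(geom$centers[v, 1L]); cx <- round(geom$centers[v, 2L])
    ry <- (cy - centre_index(ny) + 1L):(cy - centre_index(ny) + ny)
    rx <- (cx - centre_index(nx) + 1L):(cx - centre_index(nx) + nx)
    out[ry, rx] <- rsim_fuse(os[ry, rx], ui[ry, rx], fringe_freq_px,
                             cutoff_fraction)
  }
  out
}

#' @export
print.sectioned_frame <- function(x, ...) {
  cat(sprintf("sectioned frame (raw windows %s, t = %d), %dx%d px\n",
              paste(x$window, collapse = ","), x$timestamp,
              nrow(x$image), ncol(x$image)))
  invisible(x)
}
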