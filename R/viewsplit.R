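# Locating sub-image centres on the camera and segmenting frames per view.

#' Calibrate sub-image (view) centres from a bright frame
#'
#' Smooths the frame, finds local maxima, applies greedy non-maximum
#' suppression at a minimum separation of about one sub-image diameter,
#' keeps the brightest \code{expected_views} peaks, and refines each to
#' sub-pixel precision with a local intensity centroid. Ties in peak
#' intensity are broken by (row, column) order.
#'
#' @param frame calibration frame (matrix) from a bright extended or point
#'   sample.
#' @param expected_views number of views expected.
#' @param min_separation minimum centre separation in pixels (default:
#'   estimated from the frame size and the expected count).
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param refine_radius half-size of the centroid-refinement window.
#' @return \code{expected_views} x 2 matrix of (y, x) centres, sorted by
#'   (row band, column).
#' @export
calibrate_view_centers <- function(frame, expected_views,
                                   min_separation = NULL, smooth_sigma = 2,
                                   refine_radius = NULL) {
  if (diff(range(frame)) == 0)
    stop("featureless frame: no peaks to calibrate from", call. = FALSE)
  sm <- gauss_blur2(frame, smooth_sigma)
  ny <- nrow(sm); nx <- ncol(sm)
  min_separation <- min_separation %||%
    max(3, floor(0.5 * min(ny, nx) / ceiling(sqrt(expected_views))))
  refine_radius <- refine_radius %||% max(2L, ceiling(min_separation / 4))
  # local maxima over the 8-neighbourhood (interior pixels only)
  ctr <- sm[2:(ny - 1), 2:(nx - 1)]
  ismax <- ctr >= sm[1:(ny - 2), 2:(nx - 1)] & ctr >= sm[3:ny, 2:(nx - 1)] &
    ctr >= sm[2:(ny - 1), 1:(nx - 2)] & ctr >= sm[2:(ny - 1), 3:nx] &
    ctr >= sm[1:(ny - 2), 1:(nx - 2)] & ctr >= sm[1:(ny - 2), 3:nx] &
    ctr >= sm[3:ny, 1:(nx - 2)] & ctr >= sm[3:ny, 3:nx] &
    ctr > min(sm)
  pk <- which(ismax, arr.ind = TRUE) + 1L
  if (nrow(pk) == 0)
    stop("featureless frame: no peaks to calibrate from", call. = FALSE)
  val <- sm[pk]
  ord <- order(-val, pk[, 1L], pk[, 2L])
  pk <- pk[ord, , drop = FALSE]
  keep <- matrix(NA_real_, 0L, 2L)
  for (i in seq_len(nrow(pk))) {
    p <- pk[i, ]
    if (nrow(keep) == 0L ||
        all((keep[, 1L] - p[1L])^2 + (keep[, 2L] - p[2L])^2 >=
              min_separation^2))
      keep <- rbind(keep, p)
    if (nrow(keep) == expected_views) break
  }
  if (nrow(keep) < expected_views)
    stop(sprintf("found only %d candidate view centres, expected %d",
                 nrow(keep), expected_views), call. = FALSE)
  refined <- t(apply(keep, 1L, function(p) {
    ry <- max(1L, p[1L] - refine_radius):min(ny, p[1L] + refine_radius)
    rx <- max(1L, p[2L] - refine_radius):min(nx, p[2L] + refine_radius)
    w <- sm[ry, rx, drop = FALSE]
    w <- w - min(w)
    if (sum(w) == 0) return(as.numeric(p))
    c(sum(ry * rowSums(w)) / sum(w), sum(rx * colSums(w)) / sum(w))
  }))
  band <- round(refined[, 1L] / min_separation)
  refined <- refined[order(band, refined[, 2L]), , drop = FALSE]
  colnames(refined) <- c("y", "x")
  refined
}

#' Segment a camera frame into per-view sub-images
#'
#' Square crops of side \code{2 * crop_radius + 1} centred on the rounded
#' view centres, in centre order. Crops that would leave the frame raise an
#' error; nothing is silently zero-padded.
#'
#' @param frame camera frame (matrix).
#' @param centers n x 2 matrix of (y, x) view centres.
#' @param crop_radius crop half-size in pixels (default:
#'   [default_crop_radius()] of the centres).
#' @return An object of class \code{view_stack}: \code{sub_images}
#'   (array [y, x, view]), \code{centers}, \code{crop_radius}.
#' @export
segment_views <- function(frame, centers, crop_radius = NULL) {
  centers <- as.matrix(centers)
  crop_radius <- crop_radius %||% default_crop_radius(centers)
  side <- 2L * crop_radius + 1L
  nv <- nrow(centers)
  out <- array(0, c(side, side, nv))
  for (v in seq_len(nv)) {
    cy <- round(centers[v, 1L]); cx <- round(centers[v, 2L])
    ry <- (cy - crop_radius):(cy + crop_radius)
    rx <- (cx - crop_radius):(cx + crop_radius)
    if (min(ry) < 1L || min(rx) < 1L || max(ry) > nrow(frame) ||
        max(rx) > ncol(frame))
      stop(sprintf("crop for view %d (radius %d) leaves the frame", v,
                   crop_radius), call. = FALSE)
    out[, , v] <- frame[ry, rx]
  }
  structure(list(sub_images = out, centers = centers,
                 crop_radius = crop_radius), class = "view_stack")
}

#' Default crop radius from a set of view centres
#'
#' Floor of 0.45 times the minimal pairwise centre distance, which
#' guarantees non-overlapping crops.
#'
#' @param centers n x 2 matrix of centres.
#' @return Integer radius in pixels.
#' @export
default_crop_radius <- function(centers) {
  n <- nrow(centers)
  if (n < 2L) stop("need at least two centres to infer a crop radius",
                   call. = FALSE)
  dmin <- min(stats::dist(centers))
  max(1L, floor(0.45 * dmin))
}

#' @export
print.view_stack <- function(x, ...) {
  d <- dim(x$sub_images)
  cat(sprintf("view stack: %d views of %dx%d px (crop radius %d)\n",
              d[3L], d[1L], d[2L], x$crop_radius))
  invisible(x)
}
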