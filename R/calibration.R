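# PSF calibration from bead z-stacks, FWHM resolution measurement, and
# locally weighted linear regression with Gaussian distance weights.

#' Extract a measured PSF bank from a bead z-stack
#'
#' For each view and depth: threshold the sub-image at (background median +
#' k * MAD), keep the largest connected component (maximum connected
#' domain; ties broken by total intensity, then by (row, column) of the
#' component centroid), centre a fixed window on the component's centroid
#' at the depth nearest focus (the window stays fixed across depth so the
#' parallax shift of off-centre views is preserved), subtract the
#' background median, clip negatives and assemble a bank normalized with
#' the usual photon-conservation convention.
#'
#' @param z_stack_frames list of camera frames, one per depth, each imaging
#'   a single isolated bead.
#' @param centers view-centre matrix.
#' @param z_grid depths in um, one per frame.
#' @param pitch object-space pixel pitch, um.
#' @param crop_radius sub-image crop half-size.
#' @param window_radius half-size of the fixed PSF window (default:
#'   \code{crop_radius}).
#' @param threshold_k MAD multiplier of the threshold rule (default 5).
#' @return A \code{psf_bank} with \code{source = "calibrated"}.
#' @export
extract_psf_from_beads <- function(z_stack_frames, centers, z_grid, pitch,
                                   crop_radius = NULL, window_radius = NULL,
                                   threshold_k = 5) {
  stopifnot(length(z_stack_frames) == length(z_grid))
  centers <- as.matrix(centers)
  crop_radius <- crop_radius %||% default_crop_radius(centers)
  window_radius <- window_radius %||% crop_radius
  side <- 2L * window_radius + 1L
  nv <- nrow(centers)
  nz <- length(z_grid)
  iz0 <- which.min(abs(z_grid))
  psfs <- array(0, c(side, side, nz, nv))
  for (v in seq_len(nv)) {
    subs <- lapply(z_stack_frames, function(fr)
      segment_views(fr, centers, crop_radius)$sub_images[, , v])
    # fixed window centre: component centroid at the depth nearest focus
    ref <- largest_component(subs[[iz0]], threshold_k)
    if (is.null(ref))
      stop(sprintf("no component above threshold for view %d at z = %.3g um",
                   v, z_grid[iz0]), call. = FALSE)
    c0 <- round(ref$centroid)
    for (iz in seq_len(nz)) {
      comp <- largest_component(subs[[iz]], threshold_k)
      if (is.null(comp))
        stop(sprintf("no component above threshold for view %d at z = %.3g um",
                     v, z_grid[iz]), call. = FALSE)
      img <- subs[[iz]] - comp$background
      img[img < 0] <- 0
      img[!comp$mask] <- 0
      out <- matrix(0, side, side)
      ry <- (c0[1L] - window_radius):(c0[1L] + window_radius)
      rx <- (c0[2L] - window_radius):(c0[2L] + window_radius)
      ok_y <- ry >= 1L & ry <= nrow(img)
      ok_x <- rx >= 1L & rx <= ncol(img)
      out[which(ok_y), which(ok_x)] <- img[ry[ok_y], rx[ok_x]]
      psfs[, , iz, v] <- out
    }
  }
  for (iz in seq_len(nz)) {
    tot <- sum(psfs[, , iz, ])
    if (tot <= 0)
      stop(sprintf("no PSF energy at z = %.3g um", z_grid[iz]), call. = FALSE)
    psfs[, , iz, ] <- psfs[, , iz, ] / tot
  }
  ntile <- ceiling(sqrt(nv))
  mosaic <- t(vapply(seq_len(nv), function(v) {
    r <- (v - 1L) %/% ntile; c <- (v - 1L) %% ntile
    c(r * side + centre_index(side), c * side + centre_index(side))
  }, numeric(2)))
  colnames(mosaic) <- c("y", "x")
  structure(list(psfs = psfs, view_centers = mosaic,
                 pupil_offsets_na = NULL, z_grid = z_grid, pitch = pitch,
                 source = "calibrated"), class = "psf_bank")
}

#' Largest above-threshold connected component of an image
#' @noRd
largest_component <- function(img, threshold_k) {
  med <- stats::median(img)
  s <- stats::mad(img)
  thr <- med + threshold_k * (if (s > 0) s else max(1e-12, max(img) * 1e-3))
  mask <- img > thr
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  area <- tabulate(lab[lab > 0L], nbins = n)
  best <- which(area == max(area))
  if (length(best) > 1L) {            # tie: higher total intensity
    tot <- vapply(best, function(l) sum(img[lab == l]), numeric(1))
    best <- best[tot == max(tot)]
    if (length(best) > 1L) {          # then (row, column) of centroid
      cen <- t(vapply(best, function(l)
        array_centroid(ifelse(lab == l, img, 0)), numeric(2)))
      best <- best[order(cen[, 1L], cen[, 2L])]
    }
  }
  m <- lab == best[1L]
  list(mask = m, background = med,
       centroid = array_centroid(ifelse(m, img, 0)))
}

#' Full width at half maximum along one axis of a volume
#'
#' Takes the 1D intensity profile through the brightest voxel near
#' \code{center_hint} along the requested axis, finds the half-maximum
#' crossings by linear interpolation on both flanks, and returns their
#' distance in physical units. \code{axis = "lateral"} returns the mean of
#' the x and y widths.
#'
#' @param volume an \code{flfm_volume} or 3D array [y, x, z].
#' @param axis \code{"x"}, \code{"y"}, \code{"z"} or \code{"lateral"}.
#' @param center_hint optional (y, x, z) voxel indices near the peak; the
#'   peak is searched within \code{hint_radius} voxels of it.
#' @param voxel_pitch um triplet (taken from the volume when available).
#' @param hint_radius search radius around the hint, voxels.
#' @return Width in um.
#' @export
measure_fwhm <- function(volume, axis = c("lateral", "x", "y", "z"),
                         center_hint = NULL, voxel_pitch = NULL,
                         hint_radius = 4L) {
  axis <- match.arg(axis)
  if (inherits(volume, "flfm_volume")) {
    voxel_pitch <- voxel_pitch %||% volume$voxel_pitch
    volume <- volume$data
  }
  if (is.null(voxel_pitch)) stop("'voxel_pitch' is required", call. = FALSE)
  if (axis == "lateral")
    return(mean(c(
      measure_fwhm(volume, "y", center_hint, voxel_pitch, hint_radius),
      measure_fwhm(volume, "x", center_hint, voxel_pitch, hint_radius))))
  d <- dim(volume)
  if (is.null(center_hint)) {
    peak <- arrayInd(which.max(volume), d)[1L, ]
  } else {
    h <- round(center_hint)
    lo <- pmax(h - hint_radius, 1L); hi <- pmin(h + hint_radius, d)
    sub <- volume[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
    peak <- arrayInd(which.max(sub), dim(sub))[1L, ] + lo - 1L
  }
  ax <- match(axis, c("y", "x", "z"))
  prof <- switch(ax, volume[, peak[2L], peak[3L]],
                 volume[peak[1L], , peak[3L]],
                 volume[peak[1L], peak[2L], ])
  fwhm_of_profile(prof, peak[ax]) * voxel_pitch[ax]
}

#' Half-max crossing width of a 1D profile, in samples
#' @noRd
fwhm_of_profile <- function(prof, ipk = which.max(prof)) {
  pk <- prof[ipk]
  half <- pk / 2
  n <- length(prof)
  if (n == 1L) return(1)
  left <- NA_real_
  if (ipk > 1L) for (i in seq.int(ipk, 2L)) {
    if (prof[i - 1L] < half && prof[i] >= half) {
      left <- (i - 1L) + (half - prof[i - 1L]) / (prof[i] - prof[i - 1L])
      break
    }
  }
  right <- NA_real_
  if (ipk < n) for (i in seq.int(ipk, n - 1L)) {
    if (prof[i + 1L] < half && prof[i] >= half) {
      right <- i + (prof[i] - half) / (prof[i] - prof[i + 1L])
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    # degenerate single-sample impulse: width of one sample
    if (sum(prof > half) == 1L && prof[ipk] > 0 &&
        (ipk == 1L || prof[ipk - 1L] < half) &&
        (ipk == n || prof[ipk + 1L] < half)) return(1)
    stop("profile does not fall below half maximum on both sides ",
         "(truncated peak)", call. = FALSE)
  }
  right - left
}

#' Locally weighted linear regression with a Gaussian distance kernel
#'
#' At each query point \code{x0} solves the weighted least-squares problem
#' \deqn{\min_{\alpha,\beta} \sum_i K_d(x_0, x_i)\,
#'   [y_i - \alpha - \beta x_i]^2,\qquad
#'   K_d(x_0, x_i) = \exp\!\left(-\frac{(x_0-x_i)^2}{2 d^2}\right),}
#' using all points (a Gaussian kernel, not a nearest-neighbour span). The
#' fitted value is \eqn{y_0 = \hat\alpha + \hat\beta x_0}; the spread
#' \eqn{\sigma_{x_0} = \sqrt{F / \sum_i K_d}} with \eqn{F} the weighted
#' residual sum of squares of the final fit (no degrees-of-freedom
#' correction), and the 95% band is \eqn{y_0 \pm 2\sigma_{x_0}}.
#'
#' @param x,y observations (at least two distinct x values).
#' @param query_points points at which to evaluate (default: sorted unique
#'   x).
#' @param d kernel bandwidth in the units of x (default 10, matching
#'   micron-scale resolution curves).
#' @return An object of class \code{flfm_loess}: data frame \code{fit}
#'   with columns x0, y0, sigma, ci_low, ci_high; bandwidth \code{d}.
#' @export
loess_fit <- function(x, y, query_points = NULL, d = 10) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (length(unique(x)) < 2L)
    stop("degenerate design: all x identical", call. = FALSE)
  stopifnot_scalar_pos(d, "d")
  query_points <- query_points %||% sort(unique(x))
  X <- cbind(1, x)
  rows <- lapply(query_points, function(x0) {
    w <- exp(-(x0 - x)^2 / (2 * d^2))
    fit <- stats::lm.wfit(X, y, w)
    y0 <- sum(stats::coef(fit) * c(1, x0))
    Fval <- sum(w * fit$residuals^2)
    sigma <- sqrt(Fval / sum(w))
    data.frame(x0 = x0, y0 = y0, sigma = sigma,
               ci_low = y0 - 2 * sigma, ci_high = y0 + 2 * sigma)
  })
  structure(list(fit = do.call(rbind, rows), d = d,
                 data = data.frame(x = x, y = y)),
            class = "flfm_loess")
}

#' @export
print.flfm_loess <- function(x, ...) {
  cat(sprintf("locally weighted linear fit (Gaussian kernel, d = %.3g): %d query points\n",
              x$d, nrow(x$fit)))
  print(utils::head(x$fit, 5L), row.names = FALSE)
  if (nrow(x$fit) > 5L) cat("  ...\n")
  invisible(x)
}

#' @export
predict.flfm_loess <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fit$y0)
  x0 <- if (is.data.frame(newdata)) newdata[[1L]] else newdata
  refit <- loess_fit(object$data$x, object$data$y, query_points = x0,
                     d = object$d)
  refit$fit$y0
}

#' @export
plot.flfm_loess <- function(x, ...) {
  with(x$fit, {
    plot(x$data$x, x$data$y, pch = 16, col = "grey40",
         xlab = "position", ylab = "value", ...)
    graphics::polygon(c(x0, rev(x0)), c(ci_low, rev(ci_high)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(x0, y0, col = "steelblue", lwd = 2)
  })
  invisible(x)
}

#' Bead-wise resolution table and fitted resolution-vs-depth curves
#'
#' Measures the lateral and axial FWHM of each reconstructed bead and fits
#' both against bead depth with [loess_fit()] (Gaussian kernel, 95% bands).
#'
#' @param volume reconstructed \code{flfm_volume} containing the beads.
#' @param bead_positions n x 3 matrix/data frame of bead (y, x, z) voxel
#'   indices (e.g. from phantom ground truth).
#' @param d kernel bandwidth in um.
#' @param csv optional path; when given, the table is written as CSV.
#' @return List with \code{table} (data frame: position in um, lateral and
#'   axial FWHM), \code{lateral_fit}, \code{axial_fit}.
#' @export
resolution_report <- function(volume, bead_positions, d = 10, csv = NULL) {
  stopifnot(inherits(volume, "flfm_volume"))
  bead_positions <- as.matrix(bead_positions)
  if (nrow(bead_positions) < 5L)
    stop("need at least 5 beads for a resolution report", call. = FALSE)
  pitch <- volume$voxel_pitch
  dims <- dim(volume$data)
  rows <- lapply(seq_len(nrow(bead_positions)), function(b) {
    hint <- bead_positions[b, ]
    data.frame(
      y_um = (hint[1L] - centre_index(dims[1L])) * pitch[1L],
      x_um = (hint[2L] - centre_index(dims[2L])) * pitch[2L],
      z_um = volume$z_grid[round(hint[3L])],
      fwhm_lateral_um = measure_fwhm(volume, "lateral", hint),
      fwhm_axial_um = measure_fwhm(volume, "z", hint))
  })
  tab <- do.call(rbind, rows)
  lat <- loess_fit(tab$z_um, tab$fwhm_lateral_um, d = d)
  axi <- loess_fit(tab$z_um, tab$fwhm_axial_um, d = d)
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  list(table = tab, lateral_fit = lat, axial_fit = axi)
}
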