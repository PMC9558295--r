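# Multi-view Richardson-Lucy 3D deconvolution.

#' Multi-view Richardson-Lucy deconvolution
#'
#' Reconstructs a 3D volume from per-view sub-images and a PSF bank by the
#' multiplicative maximum-likelihood update for Poisson data,
#' \deqn{x \leftarrow x \cdot
#'   \frac{\sum_v H_v^T (y_v / \max((H x)_v, \epsilon))}
#'        {\sum_v H_v^T 1},}
#' where \eqn{H} is the per-view depth-summed convolution forward model and
#' \eqn{H^T} its exact adjoint (both FFT-based with zero-padding to the
#' linear-convolution size, so parallax shifts never wrap around). The
#' iteration preserves non-negativity; exactly \code{n_iter} iterations are
#' run (no early stopping), and the Poisson log-likelihood
#' \eqn{\sum y \log(Hx) - Hx} is recorded per iteration.
#'
#' @param views a \code{view_stack} from [segment_views()] or a 3D array
#'   [y, x, view] matching the bank's PSF grid.
#' @param bank a \code{psf_bank}.
#' @param n_iter number of iterations (default 30).
#' @param init \code{"backproject"} starts from a flat volume at the mean
#'   of the back-projected data; \code{"flat"} from all-ones times the mean
#'   data level.
#' @param epsilon guard added to ratios and the sensitivity (default 1e-12).
#' @return An \code{flfm_volume} with the per-iteration log-likelihood in
#'   \code{$loglik}.
#' @export
richardson_lucy_multiview <- function(views, bank, n_iter = 30L,
                                      init = c("backproject", "flat"),
                                      epsilon = 1e-12) {
  init <- match.arg(init)
  y <- if (inherits(views, "view_stack")) views$sub_images else views
  stopifnot(inherits(bank, "psf_bank"))
  d <- dim(bank$psfs)
  if (!all(dim(y) == c(d[1L], d[2L], d[4L])))
    stop(sprintf("views are %s but the bank expects %dx%d x %d views",
                 paste(dim(y), collapse = "x"), d[1L], d[2L], d[4L]),
         call. = FALSE)
  if (anyNA(y)) stop("NaN/NA in input views", call. = FALSE)
  nz <- d[3L]
  if (all(y == 0)) {
    warning("all-zero views: returning a zero volume", call. = FALSE)
    vol <- flfm_volume(array(0, c(d[1L], d[2L], nz)), bank$z_grid, bank$pitch)
    vol$loglik <- numeric(0)
    return(vol)
  }
  ot <- make_otf_stack(bank)
  sens <- adjoint_views(array(1, dim(y)), ot)
  x <- if (init == "backproject") {
    bp <- adjoint_views(y, ot)
    array(max(mean(bp), epsilon), dim(sens))
  } else array(max(mean(y), epsilon), dim(sens))
  ll <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    fwd <- forward_views(x, ot)
    fwd_c <- pmax(fwd, epsilon)
    ll[it] <- sum(y * log(fwd_c) - fwd)
    x <- x * adjoint_views(y / fwd_c, ot) / pmax(sens, epsilon)
    x[x < 0] <- 0          # guard against FFT round-off
  }
  vol <- flfm_volume(x, bank$z_grid, bank$pitch)
  vol$loglik <- ll
  vol
}

#' Reconstruct a sequence of sectioned frames into volumes
#'
#' Segments each frame at the given view centres and deconvolves it; a
#' 3n-frame raw acquisition sectioned with interleaved windows therefore
#' yields 3n - 2 volumes.
#'
#' @param frames list of \code{sectioned_frame} objects (or plain
#'   matrices).
#' @param centers n x 2 view-centre matrix (default: the bank's).
#' @param bank a \code{psf_bank}.
#' @param n_iter Richardson-Lucy iterations per frame.
#' @param crop_radius crop half-size (default: matched to the bank's PSF
#'   grid).
#' @param ... passed to [richardson_lucy_multiview()].
#' @return List of \code{flfm_volume}s.
#' @export
reconstruct_sequence <- function(frames, bank, centers = NULL,
                                 n_iter = 30L, crop_radius = NULL, ...) {
  stopifnot(inherits(bank, "psf_bank"))
  centers <- centers %||% bank$view_centers
  d <- dim(bank$psfs)
  if (d[1L] %% 2L == 0L)
    stop("reconstruct_sequence needs an odd PSF grid to define crops",
         call. = FALSE)
  crop_radius <- crop_radius %||% ((d[1L] - 1L) %/% 2L)
  lapply(frames, function(f) {
    img <- if (inherits(f, "sectioned_frame")) f$image else f
    vs <- segment_views(img, centers, crop_radius)
    richardson_lucy_multiview(vs, bank, n_iter = n_iter, ...)
  })
}
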