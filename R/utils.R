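# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded generators are pure
#' functions of their arguments and never disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' FFT sample frequencies (cycles per unit), matching the unshifted FFT order
#' @noRd
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

#' Centre index of an axis under the pixel-centred convention
#' @noRd
centre_index <- function(n) floor(n / 2) + 1L

#' Shift the zero-frequency / PSF origin to the centre pixel
#' @noRd
fft_shift2 <- function(x) {
  ny <- nrow(x); nx <- ncol(x)
  sy <- centre_index(ny) - 1L
  sx <- centre_index(nx) - 1L
  x[c(seq.int(ny - sy + 1L, ny), seq_len(ny - sy)),
    c(seq.int(nx - sx + 1L, nx), seq_len(nx - sx)), drop = FALSE]
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Zero-pad a matrix into the top-left corner of an ly x lx canvas
#' @noRd
pad_to <- function(x, ly, lx, oy = 1L, ox = 1L) {
  out <- matrix(0, ly, lx)
  out[oy:(oy + nrow(x) - 1L), ox:(ox + ncol(x) - 1L)] <- x
  out
}

#' Linear `same`-size 2D convolution via zero-padded FFT.
#' Kernel is taken as centred on its centre pixel.
#' @noRd
conv2_same <- function(x, h) {
  ny <- nrow(x); nx <- ncol(x)
  ly <- stats::nextn(ny + nrow(h) - 1L)
  lx <- stats::nextn(nx + ncol(h) - 1L)
  full <- Re(ifft2(fft2(pad_to(x, ly, lx)) * fft2(pad_to(h, ly, lx))))
  cy <- centre_index(nrow(h)); cx <- centre_index(ncol(h))
  full[cy:(cy + ny - 1L), cx:(cx + nx - 1L)]
}

#' Isotropic Gaussian blur (sigma in pixels) with reflective padding
#' @noRd
gauss_blur2 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  xp <- mirror_pad(x, r)
  out <- apply(xp, 2L, function(col) stats::filter(col, k, sides = 2))
  out <- t(apply(t(out), 2L, function(row) stats::filter(row, k, sides = 2)))
  out[(r + 1L):(r + nrow(x)), (r + 1L):(r + ncol(x)), drop = FALSE]
}

#' Reflective (mirror) padding by r pixels on every side
#' @noRd
mirror_pad <- function(x, r) {
  ny <- nrow(x); nx <- ncol(x)
  iy <- c(rev(seq_len(min(r, ny))), seq_len(ny), ny + 1L - rev(seq_len(min(r, ny))))
  ix <- c(rev(seq_len(min(r, nx))), seq_len(nx), nx + 1L - rev(seq_len(min(r, nx))))
  while (length(iy) < ny + 2L * r) iy <- c(iy[1L], iy)   # tiny images
  while (length(ix) < nx + 2L * r) ix <- c(ix[1L], ix)
  x[iy, ix, drop = FALSE]
}

#' Lower-of-the-two-middles median (declared convention for even n)
#' @noRd
median_low <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

#' Intensity-weighted centroid of a matrix or 3D array, in (fractional) indices
#' @noRd
array_centroid <- function(a) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  tot <- sum(a)
  if (tot <= 0) stop("centroid of a non-positive array is undefined", call. = FALSE)
  idx <- lapply(seq_along(d), function(k) {
    m <- apply(a, k, sum)
    sum(m * seq_len(d[k])) / tot
  })
  unlist(idx)
}

#' Connected-component labelling of a 3D logical mask (6-connectivity)
#'
#' Used for small volumes (tracking, phantom checks); BFS over voxel indices.
#' @noRd
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nextlab <- 0L
  idx <- which(mask)
  strides <- c(1L, d[1L], d[1L] * d[2L])
  for (start in idx) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      for (v in cur) {
        v0 <- v - 1L
        zi <- v0 %/% strides[3L]
        rem <- v0 %% strides[3L]
        xi <- rem %/% strides[2L]
        yi <- rem %% strides[2L]
        for (ax in 1:3) {
          pos <- c(yi, xi, zi)[ax]
          for (dlt in c(-1L, 1L)) {
            p <- pos + dlt
            if (p < 0L || p >= d[ax]) next
            nb <- v + dlt * strides[ax]
            if (mask[nb] && lab[nb] == 0L) {
              lab[nb] <- nextlab
              queue <- c(queue, nb)
            }
          }
        }
      }
    }
  }
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a positive scalar", name), call. = FALSE)
  invisible(x)
}
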