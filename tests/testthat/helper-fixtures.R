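# Shared fixtures and independent oracles for the test suite.

# Small reference-geometry configuration (same optics as the shipped
# defaults, fewer views and a short z range so banks build in well under a
# second).
tiny_config <- function(n_views = 7L, z_range = 12, z_step = 3) {
  optical_config(
    f_objective = 7.2, na_objective = 1.05, f_tube = 200, f_fourier = 300,
    f_mla = 38.24, d_mla = 3, emission_wavelength = 525,
    excitation_wavelength = 470, camera_pixel_pitch = 4.5,
    n_views_requested = n_views, z_range = z_range, z_step = z_step)
}

tiny_bank <- function(n_views = 7L, grid = 33L, z_range = 12, z_step = 3,
                      pitch = 1.8, ...) {
  cfg <- tiny_config(n_views, z_range, z_step)
  der <- derive_system_parameters(cfg)
  lay <- generate_view_layout(der, cfg)
  synthesize_psf_bank(cfg, der, lay, c(grid, grid), pitch = pitch, ...)
}

# Build the three sinusoidal phase images of a uniform pixel with
# background B and modulated in-focus amplitude S (fringe phase theta at
# the pixel): I_k = B + S sin(theta + k 2 pi / 3).
phase_pixels <- function(B, S, theta, shape = c(2L, 2L)) {
  lapply(0:2, function(k)
    matrix(B + S * sin(theta + k * 2 * pi / 3), shape[1L], shape[2L]))
}

# Direct O(n^2) 'same'-size 2D convolution oracle (kernel centred on its
# centre pixel), independent of the FFT path.
conv2_same_oracle <- function(x, h) {
  ny <- nrow(x); nx <- ncol(x)
  ky <- nrow(h); kx <- ncol(h)
  cy <- floor(ky / 2) + 1L; cx <- floor(kx / 2) + 1L
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    acc <- 0
    for (a in seq_len(ky)) for (b in seq_len(kx)) {
      ii <- i - a + cy; jj <- j - b + cx
      if (ii >= 1L && ii <= ny && jj >= 1L && jj <= nx)
        acc <- acc + h[a, b] * x[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# Connected-component count oracle for a 3D mask via igraph (independent
# of the package's BFS labelling).
component_count_oracle <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(0L)
  d <- dim(mask)
  id_of <- integer(prod(d))
  id_of[idx] <- seq_along(idx)
  pos <- arrayInd(idx, d)
  strides <- c(1L, d[1L], d[1L] * d[2L])
  edges <- matrix(0L, 0L, 2L)
  for (ax in 1:3) {
    ok <- pos[, ax] < d[ax]
    nb_lin <- idx[ok] + strides[ax]
    has <- id_of[nb_lin] > 0L
    edges <- rbind(edges, cbind(id_of[idx[ok][has]], id_of[nb_lin[has]]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$no
}

# Expected number of merged bead clusters from ground-truth centres:
# single-linkage components with centres closer than one diameter merge.
expected_bead_components <- function(centers_um, diameter_um) {
  n <- nrow(centers_um)
  dmat <- as.matrix(stats::dist(centers_um))
  adj <- dmat < diameter_um
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$no
}

# Weighted least-squares oracle: explicit 2x2 normal equations at one
# query point with Gaussian distance weights.
wls_oracle <- function(x, y, x0, d) {
  w <- exp(-(x0 - x)^2 / (2 * d^2))
  sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
  sy <- sum(w * y); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  a <- (sxx * sy - sx * sxy) / det
  b <- (sw * sxy - sx * sy) / det
  res <- y - a - b * x
  list(y0 = a + b * x0, sigma = sqrt(sum(w * res^2) / sw))
}
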