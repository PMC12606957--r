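# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Bloch oracle iterates rotation matrices to
# steady state, and the DFT oracle evaluates the nonuniform Fourier sum
# directly.

# Brute-force Bloch iteration for a phase-cycled bSSFP sequence: RF pulses
# about an axis advanced by `inc_deg` per TR, free precession and relaxation
# between pulses, signal read at TE and demodulated by the RF phase.
bloch_bssfp <- function(m0, t1, t2, offres_hz, tr, te, flip_deg, inc_deg,
                        n_tr = 1500) {
  a <- flip_deg * pi / 180
  rotx <- function(v, a) c(v[1], cos(a) * v[2] - sin(a) * v[3],
                           sin(a) * v[2] + cos(a) * v[3])
  rotz <- function(v, p) c(cos(p) * v[1] - sin(p) * v[2],
                           sin(p) * v[1] + cos(p) * v[2], v[3])
  E1 <- exp(-tr / t1); E2 <- exp(-tr / t2)
  w <- 2 * pi * offres_hz * 1e-3  # rad/ms
  M <- c(0, 0, m0)
  phi <- 0
  for (j in seq_len(n_tr)) {
    phi <- (inc_deg * pi / 180) * (j - 1)
    M <- rotz(rotx(rotz(M, -phi), a), phi)
    if (j == n_tr) {
      Mte <- rotz(c(M[1] * exp(-te / t2), M[2] * exp(-te / t2), 0), w * te)
      return(complex(real = Mte[1], imaginary = Mte[2]) * exp(-1i * phi))
    }
    M <- rotz(c(M[1] * E2, M[2] * E2, m0 + (M[3] - m0) * E1), w * tr)
  }
}

# Direct nonuniform DFT: f(k_j) = sum_x img(x) exp(-i 2 pi k_j . x) with
# voxel centres at (index - n/2) * dx. Small grids only.
nudft_oracle <- function(img, coords, dx) {
  n <- dim(img)
  cw <- lapply(n, function(m) (seq_len(m) - 1 - m / 2) * dx)
  g <- expand.grid(x = cw[[1]], y = cw[[2]], z = cw[[3]])
  vapply(seq_len(nrow(coords)), function(j) {
    ph <- exp(-2i * pi * (g$x * coords[j, 1] + g$y * coords[j, 2] +
                            g$z * coords[j, 3]))
    sum(img * array(ph, dim = n))
  }, complex(1))
}

nudft_adjoint_oracle <- function(vals, coords, n, dx, weights = NULL) {
  if (!is.null(weights)) vals <- vals * weights
  cw <- (seq_len(n) - 1 - n / 2) * dx
  g <- expand.grid(x = cw, y = cw, z = cw)
  out <- vapply(seq_len(nrow(g)), function(v) {
    sum(vals * exp(2i * pi * (g$x[v] * coords[, 1] + g$y[v] * coords[, 2] +
                                g$z[v] * coords[, 3])))
  }, complex(1))
  array(out, dim = rep(n, 3))
}

# Homogeneous-compartment phantom on a small grid, with a caller-supplied
# off-resonance array or constant.
slab_phantom <- function(n = 16, dx = 2, conc = 145, offres = 0,
                         t2star = 50, slab = NULL) {
  cmap <- array(0, dim = rep(n, 3))
  if (is.null(slab)) slab <- list(x = 5:(n - 4), y = 5:(n - 4),
                                  z = (n %/% 3):(2 * n %/% 3))
  cmap[slab$x, slab$y, slab$z] <- conc
  om <- array(0, dim = rep(n, 3))
  om[] <- offres
  aff <- diag(c(dx, dx, dx, 1))
  aff[1:3, 4] <- -(n %/% 2) * dx
  structure(list(
    concentration_map = cmap,
    t1_map = array(60, dim = rep(n, 3)), t2_map = array(55, dim = rep(n, 3)),
    t2star_map = array(t2star, dim = rep(n, 3)), offres_map = om,
    label_map = array(0L, dim = rep(n, 3)), masks = list(),
    affine = aff, voxel_size_mm = dx, spec = NULL),
    class = "phantom_volume")
}
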