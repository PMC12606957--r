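#' Plan a gridding NUFFT
#'
#' Kaiser-Bessel gridding with 2x oversampling; the apodization correction is
#' computed numerically as the DFT of the sampled kernel, so the forward
#' transform approximates the exact nonuniform DFT
#' `f(k) = sum_x img(x) exp(-i 2 pi k . x)` with voxel centres at
#' `x = (index - n/2) * voxel_size` per axis (volume centred on the origin).
#'
#' @param grid_shape integer length-3 (or scalar) voxels per axis; even.
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param osf oversampling factor.
#' @param width kernel support in oversampled grid cells.
#' @return object of class `nufft_plan`.
#' @keywords internal
#' @export
nufft_plan <- function(grid_shape, voxel_size_mm, osf = 2, width = 6) {
  if (length(grid_shape) == 1) grid_shape <- rep(grid_shape, 3)
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape %% 2 != 0)) stop("grid_shape must be even per axis")
  nos <- as.integer(round(osf * grid_shape))
  nos <- nos + nos %% 2
  beta <- pi * sqrt((width / osf)^2 * (osf - 0.5)^2 - 0.8)
  apod <- lapply(seq_len(3), function(ax) {
    n <- grid_shape[ax]; no <- nos[ax]
    kv <- numeric(no)
    off <- seq(-width, width)
    u <- abs(off)
    w <- ifelse(u <= width / 2,
                besselI(beta * sqrt(pmax(0, 1 - (2 * off / width)^2)), 0), 0)
    idx <- (off %% no) + 1
    for (j in seq_along(off)) kv[idx[j]] <- kv[idx[j]] + w[j]
    A <- Re(stats::fft(kv))
    A[c((no - n / 2 + 1):no, 1:(n / 2))]   # centred indices -n/2 .. n/2-1
  })
  structure(list(n = grid_shape, nos = nos, dx = voxel_size_mm,
                 width = width, beta = beta, apod = apod),
            class = "nufft_plan")
}

# Centred (-n/2..n/2-1) <-> unshifted FFT index maps.
unshift_idx <- function(n) ((seq_len(n) - 1 - n / 2) %% n) + 1

apod3 <- function(plan) {
  outer(outer(plan$apod[[1]], plan$apod[[2]]), plan$apod[[3]])
}

# Exact path for on-grid (Cartesian) coordinates: k * (n * dx) integer.
cartesian_bins <- function(plan, coords, tol = 1e-6) {
  u <- sweep(coords * plan$dx, 2, plan$n, `*`)
  r <- round(u)
  if (max(abs(u - r)) > tol) return(NULL)
  if (any(abs(r) > plan$n / 2)) return(NULL)
  m <- sweep(r, 2, plan$n, `%%`)      # 0-based unshifted frequency index
  1 + m[, 1] + plan$n[1] * (m[, 2] + plan$n[2] * m[, 3])
}

#' Forward NUFFT (image to nonuniform k-space)
#'
#' Exact FFT sub-sampling is used when every coordinate lies on the image's
#' DFT grid (Cartesian trajectories); Kaiser-Bessel gridding otherwise.
#'
#' @param img complex (or numeric) 3D array matching the plan's grid.
#' @param plan a [nufft_plan()].
#' @param coords n x 3 matrix of k-space coordinates (cycles/mm).
#' @return complex vector of samples.
#' @keywords internal
#' @export
nufft_forward <- function(img, plan, coords) {
  stopifnot(all(dim(img) == plan$n))
  bins <- cartesian_bins(plan, coords)
  if (!is.null(bins)) {
    buf <- array(0 + 0i, dim = plan$n)
    buf[unshift_idx(plan$n[1]), unshift_idx(plan$n[2]),
        unshift_idx(plan$n[3])] <- img
    spec <- stats::fft(buf)
    return(spec[bins])
  }
  pre <- img / apod3(plan)
  buf <- array(0 + 0i, dim = plan$nos)
  ii <- lapply(seq_len(3), function(ax)
    ((seq_len(plan$n[ax]) - 1 - plan$n[ax] / 2) %% plan$nos[ax]) + 1)
  buf[ii[[1]], ii[[2]], ii[[3]]] <- pre
  spec <- stats::fft(buf)
  u <- sweep(coords * plan$dx, 2, plan$nos, `*`)
  .kb_interp3(as.vector(spec), plan$nos, u, plan$width, plan$beta)
}

#' Adjoint NUFFT (nonuniform k-space to image)
#'
#' Computes `sum_j w_j d_j exp(+i 2 pi k_j . x)` on the plan's grid, with
#' optional per-sample weights (density compensation).
#'
#' @param vals complex sample vector.
#' @param plan a [nufft_plan()].
#' @param coords n x 3 matrix (cycles/mm).
#' @param weights optional per-sample weights.
#' @return complex 3D array.
#' @keywords internal
#' @export
nufft_adjoint <- function(vals, plan, coords, weights = NULL) {
  if (!is.null(weights)) vals <- vals * weights
  bins <- cartesian_bins(plan, coords)
  if (!is.null(bins)) {
    buf <- array(0 + 0i, dim = plan$n)
    agg <- rowsum(cbind(Re(vals), Im(vals)), bins)
    buf[as.integer(rownames(agg))] <- complex(real = agg[, 1],
                                              imaginary = agg[, 2])
    img <- stats::fft(buf, inverse = TRUE)
    return(img[unshift_idx(plan$n[1]), unshift_idx(plan$n[2]),
               unshift_idx(plan$n[3])])
  }
  u <- sweep(coords * plan$dx, 2, plan$nos, `*`)
  grid <- array(.kb_spread3(as.complex(vals), plan$nos, u,
                            plan$width, plan$beta), dim = plan$nos)
  img <- stats::fft(grid, inverse = TRUE)
  ii <- lapply(seq_len(3), function(ax)
    ((seq_len(plan$n[ax]) - 1 - plan$n[ax] / 2) %% plan$nos[ax]) + 1)
  img[ii[[1]], ii[[2]], ii[[3]]] / apod3(plan)
}
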