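#' Reconstruction configuration
#'
#' @param offsets_hz demodulation frequency sweep (Hz); default -100 to
#'   +200 Hz in 20 Hz steps (16 frames).
#' @param method "adjoint" (density-compensated gridding) or "cg"
#'   (conjugate-gradient solution of the normal equations).
#' @param cg_tolerance relative residual stopping tolerance.
#' @param cg_max_iter maximum CG iterations.
#' @param output_grid voxels per axis of the reconstruction grid; default
#'   `fov/resolution` of the data's sequence parameters.
#' @param output_voxel_mm voxel size of the reconstruction grid; default the
#'   sequence resolution.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(offsets_hz = seq(-100, 200, by = 20),
                         method = c("adjoint", "cg"),
                         cg_tolerance = 1e-6, cg_max_iter = 20,
                         output_grid = NULL, output_voxel_mm = NULL) {
  method <- match.arg(method)
  stopifnot(length(offsets_hz) >= 1, cg_tolerance > 0, cg_max_iter >= 1)
  structure(list(offsets_hz = offsets_hz, method = method,
                 cg_tolerance = cg_tolerance,
                 cg_max_iter = as.integer(cg_max_iter),
                 output_grid = output_grid, output_voxel_mm = output_voxel_mm),
            class = "recon_config")
}

recon_plan <- function(kspace, config) {
  p <- kspace$params
  n <- config$output_grid
  dx <- config$output_voxel_mm
  if (is.null(dx)) dx <- p$resolution_mm
  if (is.null(n)) n <- round(p$fov_mm / dx)
  nufft_plan(n, dx)
}

#' Reconstruct one phase cycle at one demodulation offset
#'
#' Samples are demodulated by `exp(-i 2 pi offset t)` using the per-sample
#' readout timestamps (readout-time phase evolution is what causes the
#' off-resonance blurring the sweep corrects), then reconstructed either by
#' the density-weighted adjoint NUFFT or by conjugate gradients on the
#' density-weight-preconditioned normal equations. Non-convergence within
#' `cg_max_iter` attaches a warning status to the result (attribute
#' `cg_converged`), it is not silent.
#'
#' @param kspace a [sample_kspace()] result.
#' @param cycle_index which phase cycle (1-based).
#' @param offset_hz demodulation offset (Hz).
#' @param config a [recon_config()].
#' @return complex 3D array on the output grid.
#' @export
reconstruct_cycle <- function(kspace, cycle_index, offset_hz,
                              config = recon_config()) {
  stopifnot(is.finite(offset_hz),
            cycle_index >= 1, cycle_index <= ncol(kspace$samples))
  traj <- kspace$trajectory
  d <- kspace$samples[, cycle_index] *
    exp(-1i * 2 * pi * offset_hz * traj$timestamps_ms * 1e-3)
  plan <- recon_plan(kspace, config)
  if (config$method == "adjoint")
    return(nufft_adjoint(d, plan, traj$coords, traj$weights))
  # CG on A^H W A x = A^H W d  (W = density weights as preconditioner).
  AH <- function(y) nufft_adjoint(y, plan, traj$coords, traj$weights)
  A <- function(x) nufft_forward(x, plan, traj$coords)
  b <- AH(d)
  x <- array(0 + 0i, dim = dim(b))
  r <- b
  p_ <- r
  rs <- sum(Mod(r)^2)
  b0 <- sqrt(sum(Mod(b)^2))
  converged <- FALSE
  if (b0 == 0) { converged <- TRUE } else {
    for (it in seq_len(config$cg_max_iter)) {
      Ap <- AH(A(p_))
      alpha <- rs / Re(sum(Conj(p_) * Ap))
      x <- x + alpha * p_
      r <- r - alpha * Ap
      rs_new <- sum(Mod(r)^2)
      if (sqrt(rs_new) / b0 < config$cg_tolerance) { converged <- TRUE; break }
      p_ <- r + (rs_new / rs) * p_
      rs <- rs_new
    }
  }
  if (!converged)
    warning("CG did not reach tolerance ", config$cg_tolerance, " within ",
            config$cg_max_iter, " iterations")
  attr(x, "cg_converged") <- converged
  x
}

#' Combine phase-cycle images into F-states
#'
#' Per order n, the voxelwise complex sum of the cycle images weighted by
#' `exp(-i dphi n)` (dphi in radians), with no 1/N normalisation — the
#' discrete Fourier sum over cycles as printed. With N cycles, the N orders
#' 0, 1, ..., N-1 (mod N) form an invertible transform.
#'
#' @param cycle_images list of complex volumes, one per cycle.
#' @param increments a [make_phase_cycles()] result matching the images.
#' @param orders integer F-state orders; default c(-1, 0, 1).
#' @return object of class `fstate_set`: `images` (named list per order),
#'   `orders`, `increments_deg`.
#' @export
combine_fstates <- function(cycle_images, increments, orders = c(-1L, 0L, 1L)) {
  if (length(cycle_images) != length(increments$increments_deg))
    stop("number of images (", length(cycle_images),
         ") != number of phase-cycle increments (",
         length(increments$increments_deg), ")")
  dphi <- increments$increments_deg * pi / 180
  imgs <- lapply(orders, function(n) {
    acc <- array(0 + 0i, dim = dim(cycle_images[[1]]))
    for (j in seq_along(cycle_images))
      acc <- acc + cycle_images[[j]] * exp(-1i * dphi[j] * n)
    acc
  })
  names(imgs) <- paste0("F", orders)
  structure(list(images = imgs, orders = orders,
                 increments_deg = increments$increments_deg),
            class = "fstate_set")
}

#' Root-sum-of-squares composite of F-state images
#'
#' Voxelwise `sqrt(sum_n |F_n|^2)` over the retained orders; the composite
#' fills each cycle's banding nulls with signal from the others.
#'
#' @param fstates a [combine_fstates()] result.
#' @return non-negative numeric volume.
#' @export
rss_composite <- function(fstates) {
  stopifnot(length(fstates$images) >= 1)
  acc <- array(0, dim = dim(fstates$images[[1]]))
  for (im in fstates$images) acc <- acc + Mod(im)^2
  sqrt(acc)
}

#' Frequency-offset sweep reconstruction
#'
#' For each offset in the sweep: reconstruct every phase cycle, combine into
#' F-states, composite by root sum of squares; frames are stacked along the
#' fourth axis in ascending offset order, matching the 4D
#' `[X, Y, Z, offset]` stack layout the observers read.
#'
#' @param kspace a [sample_kspace()] result.
#' @param config a [recon_config()].
#' @param orders F-state orders for the composite.
#' @return object of class `offset_sweep_stack`: `magnitude` (4D array),
#'   `offsets_hz`, `affine`, `voxel_size_mm`.
#' @export
sweep_reconstruct <- function(kspace, config = recon_config(),
                              orders = c(-1L, 0L, 1L)) {
  stopifnot(length(config$offsets_hz) >= 1)
  offs <- sort(config$offsets_hz)
  n_cyc <- ncol(kspace$samples)
  frames <- lapply(offs, function(f) {
    cyc <- lapply(seq_len(n_cyc), function(ci)
      reconstruct_cycle(kspace, ci, f, config))
    rss_composite(combine_fstates(cyc, kspace$cycles, orders))
  })
  d3 <- dim(frames[[1]])
  mag <- array(unlist(frames), dim = c(d3, length(offs)))
  plan <- recon_plan(kspace, config)
  structure(list(magnitude = mag, offsets_hz = offs,
                 affine = phantom_affine(plan$n[1], plan$dx),
                 voxel_size_mm = plan$dx),
            class = "offset_sweep_stack")
}

#' Select the optimal frequency offset for an ROI
#'
#' Manual mode returns the caller's index; sharpness mode maximises the
#' normalised gradient energy (sum of squared finite differences divided by
#' the ROI mean intensity) within the ROI, breaking ties toward the lowest
#' offset index — automating the subjective per-ear selection.
#'
#' @param stack an [sweep_reconstruct()] result.
#' @param roi_mask logical 3D array on the stack grid.
#' @param mode "manual" or "sharpness".
#' @param index manual-mode frame index (1-based).
#' @return list with `index` and `offset_hz`.
#' @export
select_offset <- function(stack, roi_mask, mode = c("sharpness", "manual"),
                          index = NULL) {
  mode <- match.arg(mode)
  if (!any(roi_mask)) stop("roi_mask is empty")
  if (mode == "manual") {
    stopifnot(!is.null(index), index >= 1, index <= length(stack$offsets_hz))
    return(list(index = as.integer(index),
                offset_hz = stack$offsets_hz[index]))
  }
  score <- vapply(seq_along(stack$offsets_hz), function(i) {
    v <- stack$magnitude[, , , i]
    m <- mean(v[roi_mask])
    if (m <= 0) return(-Inf)
    g <- 0
    n <- dim(v)
    # dilate the ROI by one voxel so edge gradients are captured
    roi <- roi_mask | shift_or(roi_mask, 1) | shift_or(roi_mask, -1) |
      shift_or(roi_mask, 1, 2) | shift_or(roi_mask, -1, 2) |
      shift_or(roi_mask, 1, 3) | shift_or(roi_mask, -1, 3)
    dx <- v[2:n[1], , ] - v[1:(n[1] - 1), , ]
    g <- g + sum((dx * (roi[2:n[1], , ] | roi[1:(n[1] - 1), , ]))^2)
    dy <- v[, 2:n[2], ] - v[, 1:(n[2] - 1), ]
    g <- g + sum((dy * (roi[, 2:n[2], ] | roi[, 1:(n[2] - 1), ]))^2)
    dz <- v[, , 2:n[3]] - v[, , 1:(n[3] - 1)]
    g <- g + sum((dz * (roi[, , 2:n[3]] | roi[, , 1:(n[3] - 1)]))^2)
    g / m^2
  }, numeric(1))
  best <- which(score >= max(score) - 1e-12 * abs(max(score)))[1]
  list(index = as.integer(best), offset_hz = stack$offsets_hz[best])
}

#' Point-spread-function probe
#'
#' Simulates a centred point source with the given T2* applied over the
#' readout timestamps, reconstructs it, and returns the interpolated full
#' width at half maximum (mm) of the central profile, averaged over the three
#' axes. With an ideal (Cartesian, no-decay) acquisition the FWHM equals the
#' nominal resolution; finite T2* comparable to the readout broadens it.
#'
#' @param params a [sequence_params()].
#' @param trajectory a [make_trajectory()] result.
#' @param t2star_ms effective T2* during readout (ms), > 0; `Inf` allowed.
#' @param config a [recon_config()].
#' @return FWHM in mm.
#' @export
psf_probe <- function(params, trajectory, t2star_ms,
                      config = recon_config(offsets_hz = 0)) {
  stopifnot(t2star_ms > 0)
  decay <- if (is.finite(t2star_ms))
    exp(-trajectory$timestamps_ms / t2star_ms) else
    rep(1, length(trajectory$timestamps_ms))
  # unit point source at the origin: k-space is the pure decay envelope
  ks <- structure(list(samples = matrix(complex(real = decay), ncol = 1),
                       trajectory = trajectory,
                       cycles = make_phase_cycles(1), params = params,
                       noise_sd = 0, seed = 0L),
                  class = "kspace_set")
  img <- Mod(reconstruct_cycle(ks, 1, 0, config))
  plan <- recon_plan(ks, config)
  ctr <- plan$n %/% 2 + 1
  fw <- vapply(1:3, function(ax) {
    prof <- switch(ax, img[, ctr[2], ctr[3]], img[ctr[1], , ctr[3]],
                   img[ctr[1], ctr[2], ])
    profile_fwhm(prof, plan$dx)
  }, numeric(1))
  mean(fw)
}

# Interpolated FWHM of a 1D profile with its peak near the centre.
profile_fwhm <- function(prof, dx) {
  pk <- which.max(prof)
  half <- prof[pk] / 2
  left <- pk
  while (left > 1 && prof[left - 1] >= half) left <- left - 1
  xl <- if (left == 1) left else {
    # linear interpolation between left-1 (below half) and left (above)
    (left - 1) + (half - prof[left - 1]) / (prof[left] - prof[left - 1])
  }
  right <- pk
  n <- length(prof)
  while (right < n && prof[right + 1] >= half) right <- right + 1
  xr <- if (right == n) right else {
    right + (prof[right] - half) / (prof[right] - prof[right + 1])
  }
  (xr - xl) * dx
}
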