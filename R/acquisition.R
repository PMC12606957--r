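#' Sequence parameters for the phase-cycled bSSFP acquisition
#'
#' Defaults are the final research protocol: 1 ms RF pulse, 2 mm isotropic
#' resolution, 240 mm field of view, 25 degree flip, TR 14.26 / TE 1.06 ms,
#' 2 ms readout, 5 phase cycles.
#'
#' @param tr_ms repetition time (ms).
#' @param te_ms echo time (ms); must be < `tr_ms`.
#' @param flip_deg flip angle (degrees).
#' @param rf_pulse_width_ms RF pulse width (ms), metadata only.
#' @param readout_duration_ms duration of each readout (ms).
#' @param resolution_mm nominal isotropic resolution (mm).
#' @param fov_mm field of view (mm).
#' @param n_phase_cycles number of RF phase cycles (>= 1).
#' @return object of class `sequence_params`.
#' @export
sequence_params <- function(tr_ms = 14.26, te_ms = 1.06, flip_deg = 25,
                            rf_pulse_width_ms = 1, readout_duration_ms = 2,
                            resolution_mm = 2, fov_mm = 240,
                            n_phase_cycles = 5) {
  stopifnot(te_ms < tr_ms, n_phase_cycles >= 1, tr_ms > 0,
            readout_duration_ms > 0, resolution_mm > 0, fov_mm > 0)
  structure(list(tr_ms = tr_ms, te_ms = te_ms, flip_deg = flip_deg,
                 rf_pulse_width_ms = rf_pulse_width_ms,
                 readout_duration_ms = readout_duration_ms,
                 resolution_mm = resolution_mm, fov_mm = fov_mm,
                 n_phase_cycles = as.integer(n_phase_cycles)),
            class = "sequence_params")
}

#' Uniform RF phase-cycle increments
#'
#' @param n number of cycles (>= 1).
#' @return object of class `phase_cycle_set` with `increments_deg`
#'   = 360 k / n for k = 0..n-1.
#' @export
make_phase_cycles <- function(n) {
  if (length(n) != 1 || n <= 0 || n != round(n))
    stop("`n` must be a positive integer")
  structure(list(increments_deg = 360 * (seq_len(n) - 1) / n),
            class = "phase_cycle_set")
}

#' Complex bSSFP steady-state signal at the echo
#'
#' Standard balanced-SSFP steady state with the RF phase-cycling increment
#' folded into the effective per-TR precession angle
#' theta = 2 pi f TR - dphi. The returned complex value is the receiver-
#' demodulated transverse magnetisation at the echo time: T2 decay and
#' off-resonance phase are accrued to TE. The magnitude is periodic in the
#' off-resonance frequency with period 1/TR, producing the banding pattern
#' that phase cycling displaces: the signal minimum shifts by
#' (dphi/360)/TR Hz per increment step.
#'
#' Vectorised over `m0`, `t1`, `t2` and `offres_hz`.
#'
#' @param m0 equilibrium magnetisation (proportional to concentration).
#' @param t1,t2 longitudinal / transverse relaxation times (ms), > 0.
#' @param offres_hz off-resonance frequency (Hz).
#' @param params a [sequence_params()].
#' @param increment_deg RF phase-cycle increment (degrees).
#' @return complex vector/array of steady-state signals.
#' @export
bssfp_signal <- function(m0, t1, t2, offres_hz, params, increment_deg) {
  if (any(t1 <= 0) || any(t2 <= 0))
    stop("relaxation times must be positive")
  tr <- params$tr_ms; te <- params$te_ms
  E1 <- exp(-tr / t1); E2 <- exp(-tr / t2)
  a <- params$flip_deg * pi / 180
  th <- 2 * pi * offres_hz * tr * 1e-3 - increment_deg * pi / 180
  num <- m0 * (1 - E1) * sin(a) * (1 - E2 * exp(-1i * th))
  den <- (1 - E1 * cos(a)) * (1 - E2 * cos(th)) -
    E2 * (E1 - cos(a)) * (E2 - cos(th))
  # -1i: receiver phase convention matching an x-axis RF rotation.
  -1i * num / den * exp(-te / t2) * exp(1i * 2 * pi * offres_hz * te * 1e-3)
}

#' k-space sampling trajectory
#'
#' Builds the sample coordinates (cycles/mm), per-sample timestamps (ms from
#' the echo) and density-compensation weights for one of three trajectory
#' kinds:
#' \describe{
#'   \item{cartesian}{full grid enumeration at the stated resolution, all
#'     timestamps 0; the exact-FFT oracle path.}
#'   \item{radial}{centre-out spokes with quasi-uniform directions (golden-
#'     spiral on the sphere), samples uniform in |k| and in time.}
#'   \item{cones}{cone polar angles uniform in cos(angle); within each cone an
#'     Archimedean spiral-out from k = 0, samples uniform in time.}
#' }
#' Radial and cones use analytic |k|^2-proportional density weights; all
#' weights are normalised to sum to 1 so the adjoint of a point source (a
#' uniform-k signal) reconstructs a unit-peak centre response, and the
#' Cartesian adjoint equals the inverse DFT.
#'
#' @param params a [sequence_params()].
#' @param kind one of "cones", "radial", "cartesian".
#' @param n_readouts number of spokes/cones (non-Cartesian kinds); default
#'   scales with the Nyquist criterion for the stated resolution.
#' @param samples_per_readout samples along each readout.
#' @return object of class `trajectory` with fields `coords` (n x 3 matrix,
#'   cycles/mm), `timestamps_ms`, `weights`, `kind`, `params`.
#' @export
make_trajectory <- function(params, kind = c("cones", "radial", "cartesian"),
                            n_readouts = NULL, samples_per_readout = NULL) {
  kind <- match.arg(kind)
  kmax <- 1 / (2 * params$resolution_mm)
  if (kind == "cartesian") {
    n <- round(params$fov_mm / params$resolution_mm)
    dk <- 1 / params$fov_mm
    f <- (seq_len(n) - 1 - n / 2) * dk
    coords <- as.matrix(expand.grid(kx = f, ky = f, kz = f))
    dimnames(coords) <- NULL
    ts <- rep(0, nrow(coords))
    w <- rep(1 / nrow(coords), nrow(coords))
    return(structure(list(coords = coords, timestamps_ms = ts, weights = w,
                          kind = kind, params = params),
                     class = "trajectory"))
  }
  if (is.null(samples_per_readout))
    samples_per_readout <- round(params$fov_mm / params$resolution_mm)
  if (is.null(n_readouts)) {
    nk <- params$fov_mm / params$resolution_mm
    n_readouts <- ceiling(pi * nk^2 / 2)
  }
  i <- seq_len(n_readouts)
  if (kind == "radial") {
    # Golden-spiral points on the sphere: quasi-uniform spoke directions.
    z <- (2 * i - 1) / n_readouts - 1
    phi <- i * pi * (3 - sqrt(5))
    dirs <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
    r <- (seq_len(samples_per_readout) - 0.5) / samples_per_readout * kmax
    coords <- do.call(rbind, lapply(seq_len(n_readouts), function(j)
      outer(r, dirs[j, ])))
  } else {
    # Cones: polar angle uniform in cos(angle); per-cone Archimedean
    # spiral-out with radius linear in time.
    ct <- (2 * i - 1) / n_readouts - 1
    st <- sqrt(1 - ct^2)
    phi0 <- i * pi * (3 - sqrt(5))
    s <- (seq_len(samples_per_readout) - 0.5) / samples_per_readout
    r <- s * kmax
    n_turns <- 4
    coords <- do.call(rbind, lapply(seq_len(n_readouts), function(j) {
      az <- phi0[j] + 2 * pi * n_turns * s
      rho <- r * st[j]
      cbind(rho * cos(az), rho * sin(az), r * ct[j])
    }))
  }
  ts <- rep((seq_len(samples_per_readout) - 0.5) / samples_per_readout *
              params$readout_duration_ms, times = n_readouts)
  rr <- sqrt(rowSums(coords^2))
  w <- rr^2 + (kmax / samples_per_readout)^2   # floor keeps centre weight > 0
  w <- w / sum(w)
  structure(list(coords = coords, timestamps_ms = ts, weights = w,
                 kind = kind, params = params),
            class = "trajectory")
}

#' Scan-time planner
#'
#' Time per phase cycle is `n_readouts * TR`; the readout count of the
#' original protocol is unpublished, so the implied count for a given cycle
#' duration is reported rather than asserted.
#'
#' @param params a [sequence_params()].
#' @param n_readouts readouts per phase cycle.
#' @return list with `time_per_cycle_min`, `total_time_min` and
#'   `implied_readouts_for` (a function of minutes).
#' @export
scan_time <- function(params, n_readouts) {
  tpc <- n_readouts * params$tr_ms / 1000 / 60
  list(time_per_cycle_min = tpc,
       total_time_min = tpc * params$n_phase_cycles,
       implied_readouts_for = function(minutes)
         round(minutes * 60 * 1000 / params$tr_ms))
}

# Evaluate per-cycle steady-state images for a phantom (complex array).
cycle_image <- function(phantom, params, increment_deg) {
  bssfp_signal(phantom$concentration_map, phantom$t1_map, phantom$t2_map,
               phantom$offres_map, params, increment_deg)
}

#' Synthesise noisy phase-cycled k-space from a phantom
#'
#' For each phase cycle the voxelwise bSSFP steady state is evaluated with the
#' voxel's off-resonance, then transformed to k-space at the trajectory
#' coordinates. Readout-time evolution (off-resonance phase accrual
#' exp(+i 2 pi f t) and T2* decay) is modelled by segmenting the readout into
#' `n_time_bins` bins: each bin's modulated image is transformed and its
#' samples taken from that bin. Complex Gaussian noise of sd `noise_sd` is
#' added per sample, seeded.
#'
#' @param phantom a `phantom_volume`.
#' @param trajectory a [make_trajectory()] result.
#' @param params a [sequence_params()].
#' @param cycles a [make_phase_cycles()] result (defaults to
#'   `params$n_phase_cycles` uniform increments).
#' @param noise_sd complex noise standard deviation per channel (arbitrary
#'   units; applied to real and imaginary parts independently).
#' @param seed integer noise seed.
#' @param n_time_bins readout time-segmentation bins (1 = snapshot model).
#' @return object of class `kspace_set`: `samples` (complex matrix, samples x
#'   cycles), `trajectory`, `cycles`, `params`, `noise_sd`, `seed`.
#' @export
sample_kspace <- function(phantom, trajectory, params,
                          cycles = make_phase_cycles(params$n_phase_cycles),
                          noise_sd = 0, seed = 1L, n_time_bins = 4) {
  stopifnot(inherits(phantom, "phantom_volume"),
            inherits(trajectory, "trajectory"))
  if (phantom$voxel_size_mm * dim(phantom$concentration_map)[1] >
      1.01 * params$fov_mm)
    stop("phantom extends beyond the sequence field of view (aliasing): ",
         "set fov_mm to at least the phantom extent")
  ts <- trajectory$timestamps_ms
  if (trajectory$kind == "cartesian" || n_time_bins <= 1 ||
      max(ts) - min(ts) < 1e-12) {
    bins <- rep(1L, length(ts)); centres <- mean(ts)
  } else {
    br <- seq(min(ts), max(ts), length.out = n_time_bins + 1)
    bins <- pmin(findInterval(ts, br, rightmost.closed = TRUE), n_time_bins)
    centres <- (br[-1] + br[-length(br)]) / 2
  }
  plan <- nufft_plan(dim(phantom$concentration_map),
                     phantom$voxel_size_mm)
  n_samp <- nrow(trajectory$coords)
  n_cyc <- length(cycles$increments_deg)
  samples <- matrix(0 + 0i, n_samp, n_cyc)
  for (ci in seq_len(n_cyc)) {
    img0 <- cycle_image(phantom, params, cycles$increments_deg[ci])
    for (b in seq_along(centres)) {
      sel <- bins == b
      if (!any(sel)) next
      tl <- centres[b]
      img <- img0 * exp(-tl / phantom$t2star_map) *
        exp(1i * 2 * pi * phantom$offres_map * tl * 1e-3)
      samples[sel, ci] <- nufft_forward(img, plan,
                                        trajectory$coords[sel, , drop = FALSE])
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    samples <- samples +
      matrix(complex(real = rnorm(n_samp * n_cyc, sd = noise_sd),
                     imaginary = rnorm(n_samp * n_cyc, sd = noise_sd)),
             n_samp, n_cyc)
  }
  structure(list(samples = samples, trajectory = trajectory, cycles = cycles,
                 params = params, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "kspace_set")
}
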