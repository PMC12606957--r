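test_that("phase-cycle increments are uniform over 360 degrees", {
  expect_equal(make_phase_cycles(5)$increments_deg, c(0, 72, 144, 216, 288))
  expect_equal(make_phase_cycles(1)$increments_deg, 0)
  expect_equal(make_phase_cycles(4)$increments_deg, c(0, 90, 180, 270))
  expect_error(make_phase_cycles(0), "positive integer")
})

test_that("bSSFP closed form matches the Bloch-iteration oracle within 1%", {
  p <- sequence_params()
  for (inc in c(0, 72, 144)) {
    # band centre (theta = pi) and passband (theta = 0) frequencies for this
    # increment, plus two generic points
    f_band <- (180 + inc) / 360 / (p$tr_ms * 1e-3)
    f_pass <- inc / 360 / (p$tr_ms * 1e-3)
    for (f in c(f_band, f_pass, 13, -41)) {
      cf <- bssfp_signal(1, 60, 55, f, p, inc)
      bl <- bloch_bssfp(1, 60, 55, f, p$tr_ms, p$te_ms, p$flip_deg, inc)
      expect_lt(abs(Mod(cf) - Mod(bl)) / max(Mod(bl), 1e-9), 0.01)
    }
  }
})

test_that("bSSFP signal is periodic in off-resonance and linear in m0", {
  p <- sequence_params()
  f <- seq(-40, 40, by = 7)
  # banding magnitude is periodic with period 1/TR (the echo-time phase term
  # is not, so the comparison is on magnitudes)
  expect_equal(Mod(bssfp_signal(1, 60, 55, f, p, 72)),
               Mod(bssfp_signal(1, 60, 55, f + 1000 / p$tr_ms, p, 72)))
  expect_equal(bssfp_signal(0, 60, 55, 10, p, 72), 0 + 0i)
  expect_equal(bssfp_signal(3, 60, 55, 10, p, 72),
               3 * bssfp_signal(1, 60, 55, 10, p, 72))
  expect_error(bssfp_signal(1, -5, 55, 0, p, 0), "positive")
})

test_that("band minima shift by (dphi/360)/TR Hz between consecutive cycles", {
  p <- sequence_params()
  grid <- seq(-100, 200, by = 0.05)
  cyc <- make_phase_cycles(5)
  argmins <- vapply(cyc$increments_deg, function(inc)
    grid[which.min(Mod(bssfp_signal(1, 60, 55, grid, p, inc)))], numeric(1))
  expected_shift <- (72 / 360) / (p$tr_ms * 1e-3)
  period <- 1000 / p$tr_ms
  # minima recur every 1/TR, so the observed argmin shift is the expected
  # displacement modulo the period
  shifts <- diff(argmins) %% period
  expect_true(all(abs(shifts - expected_shift) < 0.2))
})

test_that("trajectories respect the Nyquist bound and sampling contracts", {
  p <- sequence_params(fov_mm = 48, resolution_mm = 2)
  kmax <- 1 / (2 * p$resolution_mm)
  for (kind in c("cartesian", "radial", "cones")) {
    tr <- make_trajectory(p, kind, n_readouts = 200)
    expect_lte(max(abs(tr$coords)), kmax + 1e-12)
    expect_true(all(tr$weights > 0))
    expect_equal(sum(tr$weights), 1)
    expect_true(all(tr$timestamps_ms >= 0 &
                      tr$timestamps_ms <= p$readout_duration_ms))
  }
  # cartesian enumerates the full grid: fov/resolution samples per axis
  tr <- make_trajectory(p, "cartesian")
  expect_equal(nrow(tr$coords), (48 / 2)^3)
  expect_equal(length(unique(tr$coords[, 1])), 24)
  expect_error(make_trajectory(p, "spiral"))
})

test_that("density-weighted adjoint of a point source is centre-peaked", {
  p <- sequence_params(fov_mm = 32, resolution_mm = 2)
  plan <- nufft_plan(16, 2)
  for (kind in c("radial", "cones")) {
    tr <- make_trajectory(p, kind, n_readouts = 400)
    img <- Mod(nufft_adjoint(rep(1 + 0i, nrow(tr$coords)), plan, tr$coords,
                             tr$weights))
    expect_equal(unname(arrayInd(which.max(img), rep(16, 3))[1, ]),
                 rep(16 / 2 + 1, 3))
  }
})

test_that("forward model matches the direct Fourier sum and is deterministic", {
  p <- sequence_params(fov_mm = 24, resolution_mm = 2)
  ph <- slab_phantom(n = 12, dx = 2, offres = 0)
  tr <- make_trajectory(p, "cartesian")
  ks <- sample_kspace(ph, tr, p, noise_sd = 0)
  img <- bssfp_signal(ph$concentration_map, ph$t1_map, ph$t2_map,
                      ph$offres_map, p, 0)
  oracle <- nudft_oracle(img, tr$coords, 2)
  expect_lt(max(abs(ks$samples[, 1] - oracle)) / max(abs(oracle)), 1e-10)

  # determinism and linearity
  ks1 <- sample_kspace(ph, tr, p, noise_sd = 0.5, seed = 11)
  ks2 <- sample_kspace(ph, tr, p, noise_sd = 0.5, seed = 11)
  expect_identical(ks1$samples, ks2$samples)
  ph2 <- ph
  ph2$concentration_map <- 2 * ph$concentration_map
  ks_dbl <- sample_kspace(ph2, tr, p, noise_sd = 0)
  expect_equal(ks_dbl$samples, 2 * ks$samples, tolerance = 1e-12)
})

test_that("k-space is conjugate-symmetric for a real offres-free phantom", {
  # the bSSFP image of a real phantom at dphi = 0, offres = 0 has a constant
  # phase, so k-space is conjugate-symmetric up to that phase
  p <- sequence_params(fov_mm = 24, resolution_mm = 2, n_phase_cycles = 1)
  ph <- slab_phantom(n = 12, dx = 2, offres = 0)
  tr <- make_trajectory(p, "cartesian")
  ks <- sample_kspace(ph, tr, p, noise_sd = 0)
  img <- bssfp_signal(145, 60, 55, 0, p, 0)
  s <- ks$samples[, 1] / (img / Mod(img))  # remove constant phase
  coords <- round(tr$coords * 24)
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  neg <- paste(-coords[, 1], -coords[, 2], -coords[, 3])
  has_pair <- neg %in% key
  m <- match(neg[has_pair], key)
  expect_lt(max(abs(s[has_pair] - Conj(s[m]))) / max(abs(s)), 1e-9)
})

test_that("scan-time planner reports implied readout counts", {
  st <- scan_time(sequence_params(), n_readouts = 1000)
  expect_equal(st$time_per_cycle_min, 1000 * 14.26 / 60000)
  expect_equal(st$total_time_min, 5 * st$time_per_cycle_min)
  expect_equal(st$implied_readouts_for(6.24), round(6.24 * 60000 / 14.26))
})
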