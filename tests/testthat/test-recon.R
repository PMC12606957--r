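make_kspace <- function(samples, trajectory, params,
                        cycles = make_phase_cycles(ncol(samples))) {
  structure(list(samples = samples, trajectory = trajectory, cycles = cycles,
                 params = params, noise_sd = 0, seed = 0L),
            class = "kspace_set")
}

test_that("gridding NUFFT agrees with the direct nonuniform DFT", {
  set.seed(42)
  n <- 12; dx <- 2
  img <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)),
               dim = rep(n, 3))
  plan <- nufft_plan(n, dx)
  coords <- matrix(runif(180, -1 / (2 * dx), 1 / (2 * dx)), ncol = 3)
  fwd <- nufft_forward(img, plan, coords)
  oracle <- nudft_oracle(img, coords, dx)
  expect_lt(max(abs(fwd - oracle)) / max(abs(oracle)), 1e-3)
  adj <- nufft_adjoint(fwd, plan, coords)
  adj_oracle <- nudft_adjoint_oracle(fwd, coords, n, dx)
  expect_lt(max(abs(adj - adj_oracle)) / max(abs(adj_oracle)), 1e-3)
})

test_that("Cartesian adjoint equals the inverse FFT oracle", {
  set.seed(1)
  n <- 12; dx <- 2
  p <- sequence_params(fov_mm = n * dx, resolution_mm = dx)
  tr <- make_trajectory(p, "cartesian")
  samples <- matrix(complex(real = rnorm(nrow(tr$coords)),
                            imaginary = rnorm(nrow(tr$coords))), ncol = 1)
  ks <- make_kspace(samples, tr, p)
  img <- reconstruct_cycle(ks, 1, 0, recon_config(offsets_hz = 0))
  oracle <- nudft_adjoint_oracle(samples[, 1], tr$coords, n, dx,
                                 tr$weights)
  expect_lt(max(abs(img - oracle)) / max(abs(oracle)), 1e-10)

  # all-zero samples reconstruct to an all-zero volume
  ks0 <- make_kspace(samples * 0, tr, p)
  expect_equal(max(Mod(reconstruct_cycle(ks0, 1, 0,
                                         recon_config(offsets_hz = 0)))), 0)
})

test_that("CG reconstruction solves the normal equations and flags stalls", {
  set.seed(2)
  n <- 12; dx <- 2
  p <- sequence_params(fov_mm = n * dx, resolution_mm = dx)
  tr <- make_trajectory(p, "cartesian")
  truth <- array(complex(real = rnorm(n^3)), dim = rep(n, 3))
  plan <- nufft_plan(n, dx)
  samples <- matrix(nufft_forward(truth, plan, tr$coords), ncol = 1)
  ks <- make_kspace(samples, tr, p)
  img <- reconstruct_cycle(ks, 1, 0, recon_config(offsets_hz = 0,
                                                  method = "cg"))
  expect_true(attr(img, "cg_converged"))
  expect_lt(max(abs(img - truth)) / max(abs(truth)), 1e-6)
  # starved iteration budget warns rather than failing silently
  tr2 <- make_trajectory(p, "radial", n_readouts = 150)
  s2 <- matrix(nufft_forward(truth, plan, tr2$coords), ncol = 1)
  expect_warning(
    img2 <- reconstruct_cycle(make_kspace(s2, tr2, p), 1, 0,
                              recon_config(offsets_hz = 0, method = "cg",
                                           cg_max_iter = 1,
                                           cg_tolerance = 1e-12)),
    "CG did not reach")
  expect_false(attr(img2, "cg_converged"))
})

test_that("F-state combination satisfies the Fourier-sum identities", {
  cyc <- make_phase_cycles(5)
  base <- array(complex(real = rnorm(8), imaginary = rnorm(8)), dim = c(2, 2, 2))
  # identical images: all signal lands in F0, scaled by the cycle count
  fs <- combine_fstates(rep(list(base), 5), cyc)
  expect_equal(fs$images$F0, 5 * base)
  expect_lt(max(Mod(fs$images$F1)), 1e-12)
  expect_lt(max(Mod(fs$images$`F-1`)), 1e-12)
  # pure first-harmonic input: F1 = N, everything else zero
  imgs <- lapply(cyc$increments_deg, function(d)
    array(exp(1i * d * pi / 180), dim = c(2, 2, 2)))
  f1 <- combine_fstates(imgs, cyc, orders = -2:2)
  expect_equal(Mod(f1$images$F1[1]), 5)
  expect_lt(Mod(f1$images$F0[1]), 1e-12)
  expect_lt(Mod(f1$images$`F-1`[1]), 1e-12)
  expect_error(combine_fstates(imgs[1:3], cyc), "number of images")
})

test_that("Parseval holds over a full set of F-state orders", {
  set.seed(3)
  cyc <- make_phase_cycles(5)
  imgs <- lapply(1:5, function(i)
    array(complex(real = rnorm(27), imaginary = rnorm(27)), dim = c(3, 3, 3)))
  fs <- combine_fstates(imgs, cyc, orders = 0:4)
  lhs <- Reduce(`+`, lapply(fs$images, function(im) Mod(im)^2))
  rhs <- 5 * Reduce(`+`, lapply(imgs, function(im) Mod(im)^2))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("RSS composite is the voxelwise Euclidean norm of the F-states", {
  fs <- structure(list(images = list(F0 = array(3, dim = c(1, 1, 1)),
                                     F1 = array(4, dim = c(1, 1, 1)),
                                     `F-1` = array(0, dim = c(1, 1, 1)))),
                  class = "fstate_set")
  expect_equal(as.vector(rss_composite(fs)), 5)
  fs0 <- structure(list(images = list(F0 = array(0 + 0i, dim = c(2, 2, 2)))),
                   class = "fstate_set")
  expect_equal(max(rss_composite(fs0)), 0)
})

test_that("sweep stack has one non-negative frame per offset in order", {
  set.seed(4)
  n <- 12
  p <- sequence_params(fov_mm = 24, resolution_mm = 2, n_phase_cycles = 3)
  tr <- make_trajectory(p, "cartesian")
  samples <- matrix(complex(real = rnorm(nrow(tr$coords) * 3),
                            imaginary = rnorm(nrow(tr$coords) * 3)), ncol = 3)
  ks <- make_kspace(samples, tr, p)
  st <- sweep_reconstruct(ks, recon_config(offsets_hz = c(40, -20, 0)))
  expect_equal(dim(st$magnitude)[4], 3)
  expect_equal(st$offsets_hz, c(-20, 0, 40))
  expect_true(all(st$magnitude >= 0))
  # a single-offset sweep equals the direct composite
  st1 <- sweep_reconstruct(ks, recon_config(offsets_hz = 0))
  cyc_imgs <- lapply(1:3, function(ci)
    reconstruct_cycle(ks, ci, 0, recon_config(offsets_hz = 0)))
  direct <- rss_composite(combine_fstates(cyc_imgs, ks$cycles))
  expect_equal(st1$magnitude[, , , 1], direct)
})

test_that("offset selection: manual indexing, sharpness tie-break, errors", {
  mag <- array(1, dim = c(4, 4, 4, 16))
  stack <- structure(list(magnitude = mag,
                          offsets_hz = seq(-100, 200, by = 20),
                          affine = diag(4)), class = "offset_sweep_stack")
  roi <- array(FALSE, dim = c(4, 4, 4)); roi[2:3, 2:3, 2:3] <- TRUE
  expect_equal(select_offset(stack, roi, "manual", index = 16)$offset_hz, 200)
  # identical frames: tie-break to the lowest index
  expect_equal(select_offset(stack, roi, "sharpness")$index, 1)
  expect_error(select_offset(stack, roi & FALSE), "empty")
})

test_that("PSF probe: ideal sampling gives the nominal resolution, finite
           T2* broadens monotonically", {
  p <- sequence_params(fov_mm = 48, resolution_mm = 2)
  trc <- make_trajectory(p, "cartesian")
  expect_equal(psf_probe(p, trc, Inf), 2, tolerance = 0.05)
  tr <- make_trajectory(p, "cones", n_readouts = 600)
  fw <- vapply(c(Inf, 4, 1), function(t2s) psf_probe(p, tr, t2s), numeric(1))
  expect_true(all(diff(fw) > 0))
  expect_gt(fw[2], 2)   # T2* comparable to the readout broadens beyond 2 mm
  expect_error(psf_probe(p, tr, -1))
})
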