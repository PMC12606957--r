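test_that("TPS reproduces an affine map with vanishing nonrigid part", {
  set.seed(10)
  f <- matrix(runif(36, -40, 40), ncol = 3)
  lm <- landmark_set(f, f + matrix(c(5, 0, 0), 12, 3, byrow = TRUE))
  tf <- fit_tps(lm)
  expect_lt(max(abs(tf$weights)), 1e-10)
  pts <- matrix(runif(300, -40, 40), ncol = 3)
  expect_lt(max(abs(tps_apply(tf, pts) -
                      (pts + matrix(c(5, 0, 0), 100, 3, byrow = TRUE)))),
            1e-6)
})

test_that("TPS interpolates every landmark exactly, both directions", {
  set.seed(11)
  f <- matrix(runif(36, -40, 40), ncol = 3)
  m <- f + matrix(rnorm(36, sd = 2), ncol = 3)
  lm <- landmark_set(f, m)
  expect_lt(max(abs(tps_apply(fit_tps(lm), f) - m)), 1e-6)
  expect_lt(max(abs(tps_apply(fit_tps(lm, "moving_to_fixed"), m) - f)), 1e-6)
})

test_that("degenerate landmark configurations are reported by name", {
  f <- matrix(runif(36, -40, 40), ncol = 3)
  fc <- cbind(f[, 1:2], 7)   # coplanar
  expect_error(fit_tps(landmark_set(fc, fc + 1)), "coplanar")
  fd <- f; fd[2, ] <- fd[1, ]
  expect_error(landmark_set(fd, fd), "duplicate")
  expect_warning(landmark_set(f[1:5, ], f[1:5, ]), "9-16")
})

test_that("held-out error of a smooth synthetic deformation stays below its
           spatial scale", {
  set.seed(12)
  warp <- function(p) p + cbind(3 * sin(p[, 2] / 25), 2 * cos(p[, 1] / 30),
                                1.5 * sin(p[, 3] / 20))
  f <- matrix(runif(36, -35, 35), ncol = 3)
  tf <- fit_tps(landmark_set(f, warp(f)))
  held <- matrix(runif(90, -30, 30), ncol = 3)
  err <- sqrt(rowSums((tps_apply(tf, held) - warp(held))^2))
  expect_lt(mean(err), 2)   # regression guard: well below the ~3 mm warp
})

test_that("resampling: identity is bit-exact, lattice shifts are exact,
           linear stays within the input range", {
  set.seed(13)
  v <- array(rnorm(18^3), dim = rep(18, 3))
  aff <- diag(c(2, 2, 2, 1))
  expect_identical(resample(v, aff, NULL, rep(18, 3), aff, "nearest"), v)
  aff2 <- aff; aff2[1, 4] <- 4   # +2 voxels along x
  sh <- resample(v, aff, NULL, rep(18, 3), aff2, "nearest")
  expect_equal(sh[1:16, , ], v[3:18, , ])
  expect_true(all(sh[17:18, , ] == 0))
  lin <- resample(v, aff, NULL, rep(18, 3), aff2, "linear")
  expect_gte(min(lin), min(min(v), 0))
  expect_lte(max(lin), max(v))
  bad <- aff; bad[1, 1] <- 0
  expect_error(resample(v, aff, NULL, rep(18, 3), bad), "singular")
})

test_that("mask transfer preserves identity and volume; tiny structures
           survive to the coarse sodium grid", {
  ph <- build_phantom(phantom_spec(grid_shape = 64, ear_offset_mm = 20))
  masks <- list(vestibule = ph$masks$vestibule_right)
  idt <- transfer_masks(masks, ph$affine, NULL, dim(ph$label_map), ph$affine)
  expect_identical(idt$masks$vestibule, masks$vestibule)
  # rigid integer-voxel translation at the same resolution conserves volume
  aff_t <- ph$affine; aff_t[1:3, 4] <- aff_t[1:3, 4] + c(3, -2, 1)
  tm_rigid <- transfer_masks(masks, ph$affine, NULL, dim(ph$label_map), aff_t)
  expect_lte(abs(tm_rigid$report$mm3_after - tm_rigid$report$mm3_before), 1)
  # to the 2 mm sodium grid: a handful of voxels survive (the printed
  # observation was a maximum of ~5 voxels for the vestibule)
  n2 <- 32
  aff2 <- diag(c(2, 2, 2, 1)); aff2[1:3, 4] <- -(n2 / 2) * 2
  tm <- transfer_masks(masks, ph$affine, NULL, rep(n2, 3), aff2)
  expect_gte(tm$report$voxels_after, 1)
  expect_lte(tm$report$voxels_after, 8)
  # a structure pushed outside the FOV warns and reports empty
  aff_far <- aff2; aff_far[1, 4] <- -500
  expect_warning(transfer_masks(masks, ph$affine, NULL, rep(8, 3), aff_far),
                 "outside FOV")
})

test_that("landmark files round-trip through delimited text", {
  set.seed(14)
  f <- matrix(runif(36, -40, 40), ncol = 3)
  lm <- landmark_set(f, f + 1, labels = paste0("pt", 1:12))
  path <- tempfile(fileext = ".csv")
  write_landmarks(lm, path)
  lm2 <- read_landmarks(path)
  expect_equal(lm2$fixed, lm$fixed)
  expect_equal(lm2$moving, lm$moving)
  expect_equal(lm2$labels, lm$labels)
})
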