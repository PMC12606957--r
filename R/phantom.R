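#' Default sodium compartment table
#'
#' One row per tissue class with sodium concentration (mM) and nominal 23Na
#' relaxation times (ms) at ultra-high field. Endolymph carries ~1.3 mM sodium
#' against ~145 mM (midpoint of the 141-148 mM physiological range) in
#' perilymph and CSF, which is the contrast the whole analysis rides on.
#' Relaxation defaults are declared assumptions (no published inner-ear 23Na
#' values exist): fluid T2* is much longer than the 2 ms readout, brain tissue
#' T2* is comparable to it, and bone contributes no visible signal.
#'
#' @return data.frame with columns `label`, `sodium_mM`, `t1_ms`, `t2_ms`,
#'   `t2star_ms` and the integer `code` used in label maps.
#' @export
compartment_table <- function() {
  tab <- data.frame(
    label = c("background", "bone", "csf", "perilymph", "endolymph", "brain"),
    code = 0:5,
    sodium_mM = c(0, 0, 145, 145, 1.3, 40),
    t1_ms = c(1, 1, 60, 60, 60, 35),
    t2_ms = c(1, 1, 55, 55, 55, 12),
    t2star_ms = c(1, 1, 50, 50, 50, 3),
    stringsAsFactors = FALSE
  )
  stopifnot(
    all(tab$sodium_mM >= 0),
    all(tab$t2star_ms <= tab$t2_ms),
    all(tab$t2_ms <= tab$t1_ms),
    tab$sodium_mM[tab$label == "endolymph"] < tab$sodium_mM[tab$label == "perilymph"]
  )
  tab
}

#' Phantom specification
#'
#' Parameters of the synthetic temporal-bone phantom. Geometry is parametric
#' solid modelling: an ellipsoidal vestibule, a conical-spiral cochlea and an
#' elongated fluid-filled internal auditory meatus (IAM) per side, mirrored
#' about the midline, embedded in bone with a midline brain compartment.
#'
#' @param grid_shape voxels per axis (scalar, isotropic grid).
#' @param voxel_size_mm isotropic voxel size of the "truth" grid.
#' @param hydrops_fraction length-2 numeric in [0,1], fraction of each side's
#'   inner-ear fluid (cochlea + vestibule) assigned to endolymph, order
#'   (left, right). A normal ear sits near 0.25; 1 is complete replacement of
#'   the inner-ear fluid by endolymph.
#' @param b0_amplitude_hz bound on the off-resonance map (Hz).
#' @param b0_length_scale_mm spatial scale of the smooth background field.
#' @param b0_boundary_amplitude_hz amplitude of the local perturbation at
#'   bone-fluid interfaces.
#' @param ear_offset_mm lateral distance from midline to each ear centre.
#' @param cochlea_scale,vestibule_scale geometry scale factors (1 = default
#'   sizes chosen to land in the observers' printed volume ranges).
#' @param seed integer seed for the phantom's random field component.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = 96, voxel_size_mm = 1,
                         hydrops_fraction = c(0.25, 0.25),
                         b0_amplitude_hz = 150, b0_length_scale_mm = 40,
                         b0_boundary_amplitude_hz = 60,
                         ear_offset_mm = 28,
                         cochlea_scale = 1, vestibule_scale = 1,
                         seed = 1L) {
  stopifnot(length(hydrops_fraction) == 2,
            all(hydrops_fraction >= 0), all(hydrops_fraction <= 1),
            grid_shape >= 16, voxel_size_mm > 0, b0_amplitude_hz >= 0)
  fov <- grid_shape * voxel_size_mm
  if (fov < 2 * (ear_offset_mm + 12))
    stop("grid_shape x voxel_size_mm does not cover both ears: need FOV >= ",
         2 * (ear_offset_mm + 12), " mm, got ", fov)
  structure(list(
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    hydrops_fraction = hydrops_fraction,
    b0_amplitude_hz = b0_amplitude_hz,
    b0_length_scale_mm = b0_length_scale_mm,
    b0_boundary_amplitude_hz = b0_boundary_amplitude_hz,
    ear_offset_mm = ear_offset_mm,
    cochlea_scale = cochlea_scale, vestibule_scale = vestibule_scale,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# World coordinates (mm, RAS+, origin at the centre voxel n/2 + 1) of every
# voxel centre along one axis; integer multiples of dx, matching the NUFFT's
# image-domain convention.
grid_coords <- function(n, dx) (seq_len(n) - 1 - n %/% 2) * dx

# RAS+ affine for a centred isotropic grid.
phantom_affine <- function(n, dx) {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(rep(dx, 3))
  aff[1:3, 4] <- -(n %/% 2) * dx
  aff
}

# Voxelise one (right-side) ear's structures; returns integer masks on the
# grid. Sizes are tuned so the cochlea lands in the printed 63-110 mm^3 range
# and the vestibule in 31-59 mm^3 at 1 mm resolution.
ear_masks <- function(spec) {
  n <- spec$grid_shape
  dx <- spec$voxel_size_mm
  cw <- grid_coords(n, dx)
  X <- array(cw, dim = c(n, n, n))
  Y <- aperm(array(cw, dim = c(n, n, n)), c(2, 1, 3))
  Z <- aperm(array(cw, dim = c(n, n, n)), c(3, 2, 1))
  ex <- spec$ear_offset_mm

  # Vestibule: ellipsoid.
  vs <- spec$vestibule_scale
  vest_c <- c(ex, 2, 0)
  vest <- ((X - vest_c[1]) / (2.3 * vs))^2 + ((Y - vest_c[2]) / (2.0 * vs))^2 +
    ((Z - vest_c[3]) / (2.0 * vs))^2 <= 1

  # Cochlea: union of spheres along a conical spiral anterior to the vestibule.
  cs <- spec$cochlea_scale
  coch_c <- c(ex + 1.5, 8.5, -1)
  tt <- seq(0, 2 * pi * 2.5, length.out = 160)
  rad <- (3.4 - 0.85 * tt / (2 * pi)) * cs
  px <- coch_c[1] + rad * cos(tt)
  py <- coch_c[2] + rad * sin(tt)
  pz <- coch_c[3] + 0.55 * cs * tt / (2 * pi)
  tube_r <- 1.05 * cs
  coch <- array(FALSE, dim = c(n, n, n))
  for (i in seq_along(tt)) {
    d2 <- (X - px[i])^2 + (Y - py[i])^2 + (Z - pz[i])^2
    coch <- coch | (d2 <= tube_r^2)
  }
  coch <- coch & !vest

  # IAM: elongated ellipsoid running medially from the inner ear.
  iam_c <- c(ex - 14, 4, 0)
  iam <- ((X - iam_c[1]) / 10)^2 + ((Y - iam_c[2]) / 3.2)^2 +
    ((Z - iam_c[3]) / 3.2)^2 <= 1
  iam <- iam & !vest & !coch

  # Petrous bone shell surrounding the ear structures.
  bone_c <- c(ex + 1, 5, 0)
  bone <- ((X - bone_c[1]) / 14)^2 + ((Y - bone_c[2]) / 13)^2 +
    ((Z - bone_c[3]) / 10)^2 <= 1
  bone <- bone & !vest & !coch & !iam

  list(vestibule = vest, cochlea = coch, iam = iam, bone = bone,
       centres = list(vestibule = vest_c, cochlea = coch_c, iam = iam_c))
}

# Mirror about the x = 0 plane (the centre voxel column maps to itself;
# the first voxel column, coordinate -n/2 mm, has no partner and is cleared —
# structures never touch the volume boundary).
mirror_x <- function(m) {
  n <- dim(m)[1]
  out <- m
  out[1, , ] <- if (is.logical(m)) FALSE else 0
  out[2:n, , ] <- m[n:2, , ]
  out
}

# Deterministic endolymph assignment: within each structure, the given
# fraction of fluid voxels closest to the structure's endolymphatic core
# becomes endolymph; ties broken by voxel index. Total fluid voxel count is
# independent of the fraction.
assign_endolymph <- function(mask, centre, frac, coords) {
  idx <- which(mask)
  if (length(idx) == 0 || frac <= 0) return(integer(0))
  k <- round(frac * length(idx))
  if (k == 0) return(integer(0))
  ijk <- arrayInd(idx, dim(mask))
  d2 <- (coords[ijk[, 1]] - centre[1])^2 + (coords[ijk[, 2]] - centre[2])^2 +
    (coords[ijk[, 3]] - centre[3])^2
  ord <- order(d2, idx)
  idx[ord[seq_len(min(k, length(idx)))]]
}

# Separable Gaussian blur via FFT (periodic boundaries are harmless here:
# the perturbation sources sit well inside the volume).
gauss_blur3 <- function(vol, sigma_vox) {
  if (sigma_vox <= 0) return(vol)
  dims <- dim(vol)
  out <- vol
  for (ax in 1:3) {
    n <- dims[ax]
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    g <- exp(-x^2 / (2 * sigma_vox^2))
    g <- g / sum(g)
    G <- fft(g)
    out <- apply_axis_fft(out, ax, G)
  }
  Re(out)
}

apply_axis_fft <- function(vol, ax, G) {
  perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  v <- aperm(vol, perm)
  d <- dim(v)
  m <- matrix(v, nrow = d[1])
  m <- mvfft(mvfft(m) * G, inverse = TRUE) / d[1]
  v <- array(m, dim = d)
  aperm(v, order(perm))
}

#' Build a synthetic temporal-bone sodium phantom
#'
#' Voxelises both ears (mirror-symmetric geometry), assigns per-voxel sodium
#' concentration and relaxation maps from [compartment_table()], expands the
#' endolymphatic space at the expense of perilymph according to the per-side
#' hydrops fraction, and synthesises an off-resonance (B0) map as a smooth
#' low-order random polynomial plus a Gaussian-blurred perturbation at
#' bone-fluid boundaries, clamped to the specified amplitude.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_volume`: arrays `concentration_map` (mM),
#'   `t1_map`/`t2_map`/`t2star_map` (ms), `offres_map` (Hz), `label_map`
#'   (integer codes per [compartment_table()]), named `masks` (per structure
#'   per side), `affine`, `voxel_size_mm` and the originating `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_shape
  dx <- spec$voxel_size_mm
  tab <- compartment_table()
  code <- function(lab) tab$code[tab$label == lab]

  right <- ear_masks(spec)
  masks <- list(
    cochlea_right = right$cochlea, vestibule_right = right$vestibule,
    iam_right = right$iam,
    cochlea_left = mirror_x(right$cochlea), vestibule_left = mirror_x(right$vestibule),
    iam_left = mirror_x(right$iam)
  )
  bone <- right$bone | mirror_x(right$bone)

  lab <- array(code("background"), dim = c(n, n, n))
  cw <- grid_coords(n, dx)
  # Midline brain slab (posterior fossa stand-in).
  X <- array(cw, dim = c(n, n, n))
  Y <- aperm(array(cw, dim = c(n, n, n)), c(2, 1, 3))
  Z <- aperm(array(cw, dim = c(n, n, n)), c(3, 2, 1))
  brain <- (abs(X) < spec$ear_offset_mm - 16) & (abs(Y) < 0.4 * n * dx / 2) &
    (abs(Z) < 0.4 * n * dx / 2)
  lab[brain] <- code("brain")
  lab[bone] <- code("bone")
  lab[masks$iam_right | masks$iam_left] <- code("csf")
  fluid_r <- masks$cochlea_right | masks$vestibule_right
  fluid_l <- masks$cochlea_left | masks$vestibule_left
  lab[fluid_r | fluid_l] <- code("perilymph")

  # Endolymph assignment per structure per side. The left-side selection is
  # computed on the right-side masks (at the left fraction) and mirrored, so
  # equal fractions give exactly mirror-symmetric concentration maps.
  hl <- spec$hydrops_fraction[1]; hr <- spec$hydrops_fraction[2]
  endo_right <- c(
    assign_endolymph(masks$cochlea_right, right$centres$cochlea, hr, cw),
    assign_endolymph(masks$vestibule_right, right$centres$vestibule, hr, cw))
  endo_left_on_right <- c(
    assign_endolymph(masks$cochlea_right, right$centres$cochlea, hl, cw),
    assign_endolymph(masks$vestibule_right, right$centres$vestibule, hl, cw))
  tmp <- array(FALSE, dim = c(n, n, n))
  tmp[endo_left_on_right] <- TRUE
  endo_idx <- c(endo_right, which(mirror_x(tmp)))
  lab[endo_idx] <- code("endolymph")

  lut <- function(col) {
    v <- numeric(max(tab$code) + 1)
    v[tab$code + 1] <- tab[[col]]
    array(v[lab + 1], dim = dim(lab))
  }

  # Off-resonance: seeded low-order polynomial scaled to ~60% of the bound,
  # plus blurred bone-fluid boundary perturbation, clamped to the bound.
  rng <- local({ set.seed(spec$seed); runif(9, -1, 1) })
  L <- spec$b0_length_scale_mm
  poly <- rng[1] + rng[2] * X / L + rng[3] * Y / L + rng[4] * Z / L +
    rng[5] * (X / L)^2 + rng[6] * (Y / L)^2 + rng[7] * (Z / L)^2 +
    rng[8] * X * Y / L^2 + rng[9] * Y * Z / L^2
  if (max(abs(poly)) > 0)
    poly <- poly / max(abs(poly)) * 0.6 * spec$b0_amplitude_hz
  fluid_all <- fluid_r | fluid_l | masks$iam_right | masks$iam_left
  boundary <- bone & (
    shift_or(fluid_all, 1) | shift_or(fluid_all, -1) |
    shift_or(fluid_all, 1, 2) | shift_or(fluid_all, -1, 2) |
    shift_or(fluid_all, 1, 3) | shift_or(fluid_all, -1, 3))
  pert <- gauss_blur3(boundary * 1.0, 3 / dx)
  if (max(abs(pert)) > 0)
    pert <- pert / max(abs(pert)) * spec$b0_boundary_amplitude_hz
  offres <- poly + pert
  offres <- pmin(pmax(offres, -spec$b0_amplitude_hz), spec$b0_amplitude_hz)

  structure(list(
    concentration_map = lut("sodium_mM"),
    t1_map = lut("t1_ms"), t2_map = lut("t2_ms"), t2star_map = lut("t2star_ms"),
    offres_map = array(offres, dim = c(n, n, n)),
    label_map = lab, masks = masks,
    affine = phantom_affine(n, dx), voxel_size_mm = dx, spec = spec
  ), class = "phantom_volume")
}

# Logical shift of a 3D array along an axis (zero-filled), used for
# boundary detection.
shift_or <- function(m, by, ax = 1) {
  out <- array(FALSE, dim = dim(m))
  n <- dim(m)[ax]
  src <- seq_len(n - abs(by))
  if (by > 0) dst <- src + by else { dst <- src; src <- src + abs(by) }
  ix <- function(i) switch(ax, `1` = m[i, , , drop = FALSE],
                           `2` = m[, i, , drop = FALSE],
                           `3` = m[, , i, drop = FALSE])
  if (ax == 1) out[dst, , ] <- m[src, , ]
  if (ax == 2) out[, dst, ] <- m[, src, ]
  if (ax == 3) out[, , dst] <- m[, , src]
  out
}

#' Series of phantoms over hydrops fractions
#'
#' One phantom per fraction applied to the left side (right side held at the
#' spec's value), all other parameters and the seed fixed.
#'
#' @param spec a [phantom_spec()].
#' @param fractions numeric vector of left-side hydrops fractions in [0,1].
#' @return list of `phantom_volume` objects.
#' @export
hydrops_series <- function(spec, fractions) {
  if (length(fractions) == 0) stop("`fractions` must be non-empty")
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  lapply(fractions, function(f) {
    s <- spec
    s$hydrops_fraction[1] <- f
    build_phantom(s)
  })
}

#' Structural (T2-weighted-like) volume for a phantom
#'
#' Maps tissue classes to a proton structural contrast (fluid bright, brain
#' intermediate, bone dark) for use as the registration fixed volume and for
#' intensity-threshold segmentation.
#'
#' @param phantom a `phantom_volume`.
#' @param noise_sd additive Gaussian noise sd (same arbitrary units).
#' @param seed integer seed for the noise.
#' @return numeric 3D array on the phantom grid.
#' @export
phantom_structural <- function(phantom, noise_sd = 0, seed = 1L) {
  tab <- compartment_table()
  inten <- c(background = 0.02, bone = 0.05, csf = 1, perilymph = 1,
             endolymph = 1, brain = 0.35)
  v <- numeric(max(tab$code) + 1)
  v[tab$code + 1] <- inten[tab$label]
  out <- array(v[phantom$label_map + 1], dim = dim(phantom$label_map))
  if (noise_sd > 0) {
    set.seed(seed)
    out <- out + array(rnorm(length(out), sd = noise_sd), dim = dim(out))
  }
  out
}

#' Per-structure mask volumes in mm^3
#'
#' @param phantom a `phantom_volume`.
#' @return named numeric vector of volumes (mm^3).
#' @export
phantom_mask_volumes <- function(phantom) {
  vv <- phantom$voxel_size_mm^3
  vapply(phantom$masks, function(m) sum(m) * vv, numeric(1))
}
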