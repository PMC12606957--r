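#' Landmark pair set
#'
#' Paired control points in world millimetres: `fixed` on the structural
#' (target) volume, `moving` on the sodium volume. The paper-faithful
#' workflow uses 9-16 pairs; counts outside that range warn but proceed.
#'
#' @param fixed,moving n x 3 numeric matrices (mm).
#' @param labels optional character tags per pair.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(fixed, moving, labels = NULL) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  stopifnot(ncol(fixed) == 3, ncol(moving) == 3,
            nrow(fixed) == nrow(moving))
  if (anyDuplicated(round(fixed, 9)))
    stop("duplicate fixed landmarks: rows ",
         paste(which(duplicated(round(fixed, 9))), collapse = ", "))
  n <- nrow(fixed)
  if (n < 9 || n > 16)
    warning("landmark count ", n, " outside the 9-16 control-point range")
  if (is.null(labels)) labels <- paste0("L-", seq_len(n))
  structure(list(fixed = fixed, moving = moving, labels = labels),
            class = "landmark_set")
}

#' Read / write landmark files
#'
#' Delimited text with header `label, fx, fy, fz, mx, my, mz`, world mm.
#'
#' @param path file path.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "fx", "fy", "fz", "mx", "my", "mz")
  if (!all(need %in% names(d)))
    stop("landmark file must have columns: ", paste(need, collapse = ", "))
  landmark_set(unname(as.matrix(d[, c("fx", "fy", "fz")])),
               unname(as.matrix(d[, c("mx", "my", "mz")])), d$label)
}

#' @rdname read_landmarks
#' @param landmarks a [landmark_set()].
#' @export
write_landmarks <- function(landmarks, path) {
  d <- data.frame(label = landmarks$labels,
                  fx = landmarks$fixed[, 1], fy = landmarks$fixed[, 2],
                  fz = landmarks$fixed[, 3],
                  mx = landmarks$moving[, 1], my = landmarks$moving[, 2],
                  mz = landmarks$moving[, 3])
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Fit an interpolating 3D thin-plate spline to landmark pairs
#'
#' Radial basis kernel `|r|` (the 3D thin-plate/biharmonic kernel) plus an
#' affine part, solved with the standard bordered system and zero
#' regularisation, so every source landmark maps exactly onto its target.
#' By default the spline maps fixed-space coordinates to moving-space sample
#' locations (pull-back resampling, fixed = structural, moving = sodium);
#' `direction = "moving_to_fixed"` fits the reverse map from the same pairs.
#'
#' @param landmarks a [landmark_set()].
#' @param direction "fixed_to_moving" (default, for resampling the moving
#'   volume onto the fixed grid) or "moving_to_fixed".
#' @return object of class `tps_transform` with the affine part, the
#'   per-landmark nonrigid coefficients, and the source points.
#' @export
fit_tps <- function(landmarks, direction = c("fixed_to_moving",
                                             "moving_to_fixed")) {
  direction <- match.arg(direction)
  src <- if (direction == "fixed_to_moving") landmarks$fixed else landmarks$moving
  dst <- if (direction == "fixed_to_moving") landmarks$moving else landmarks$fixed
  n <- nrow(src)
  if (n < 4) stop("need at least 4 landmark pairs")
  dup <- duplicated(round(src, 9))
  if (any(dup))
    stop("duplicate source landmarks (rows ",
         paste(which(dup), collapse = ", "), "): singular system")
  P <- cbind(1, src)
  if (qr(P)$rank < 4) {
    stop("degenerate landmark configuration: points are coplanar or ",
         "colinear (affine basis rank ", qr(P)$rank, " < 4); offending set: ",
         paste(landmarks$labels, collapse = ", "))
  }
  K <- as.matrix(stats::dist(src, diag = TRUE, upper = TRUE))
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(dst, matrix(0, 4, 3))
  sol <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular thin-plate-spline system: ", conditionMessage(e)))
  structure(list(weights = sol[seq_len(n), , drop = FALSE],
                 affine = sol[(n + 1):(n + 4), , drop = FALSE],
                 source = src, direction = direction,
                 kernel = "r"),
            class = "tps_transform")
}

#' Apply a thin-plate-spline transform to points
#'
#' @param transform a [fit_tps()] result.
#' @param points n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of transformed coordinates.
#' @export
tps_apply <- function(transform, points) {
  points <- matrix(points, ncol = 3)
  aff <- cbind(1, points) %*% transform$affine
  # kernel distances points x landmarks
  src <- transform$source
  d2 <- outer(rowSums(points^2), rep(1, nrow(src))) +
    outer(rep(1, nrow(points)), rowSums(src^2)) -
    2 * points %*% t(src)
  U <- sqrt(pmax(d2, 0))
  aff + U %*% transform$weights
}

# voxel (0-based) -> world for a 4x4 affine
voxel_to_world <- function(ijk, affine) {
  sweep(ijk %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}
world_to_voxel <- function(xyz, affine) {
  inv <- solve(affine[1:3, 1:3])
  sweep(xyz, 2, affine[1:3, 4], `-`) %*% t(inv)
}

#' Resample a volume through a spatial transform
#'
#' Pull-back resampling: each target-grid voxel centre is mapped through the
#' transform to a source-space location and the source volume is interpolated
#' there. Locations outside the source field of view give 0. Trilinear
#' interpolation for intensities, nearest-neighbour for label volumes.
#'
#' @param volume numeric 3D array (source).
#' @param source_affine 4x4 voxel-to-world affine of `volume`.
#' @param transform a [fit_tps()] result mapping target world coordinates to
#'   source world coordinates, or NULL for the identity.
#' @param target_shape integer length-3 target grid.
#' @param target_affine 4x4 voxel-to-world affine of the target grid.
#' @param interpolation "linear" or "nearest".
#' @return numeric 3D array on the target grid.
#' @export
resample <- function(volume, source_affine, transform, target_shape,
                     target_affine, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (abs(det(target_affine)) < 1e-12) stop("target affine is singular")
  if (abs(det(source_affine)) < 1e-12) stop("source affine is singular")
  target_shape <- as.integer(target_shape)
  ijk <- as.matrix(expand.grid(i = 0:(target_shape[1] - 1),
                               j = 0:(target_shape[2] - 1),
                               k = 0:(target_shape[3] - 1)))
  xyz <- voxel_to_world(ijk, target_affine)
  if (!is.null(transform)) xyz <- tps_apply(transform, xyz)
  v <- world_to_voxel(xyz, source_affine)
  d <- dim(volume)
  out <- numeric(nrow(v))
  if (interpolation == "nearest") {
    r <- round(v)
    ok <- r[, 1] >= 0 & r[, 1] <= d[1] - 1 & r[, 2] >= 0 & r[, 2] <= d[2] - 1 &
      r[, 3] >= 0 & r[, 3] <= d[3] - 1
    idx <- 1 + r[ok, 1] + d[1] * (r[ok, 2] + d[2] * r[ok, 3])
    out[ok] <- volume[idx]
  } else {
    f <- floor(v)
    w <- v - f
    ok <- f[, 1] >= 0 & f[, 1] <= d[1] - 2 & f[, 2] >= 0 & f[, 2] <= d[2] - 2 &
      f[, 3] >= 0 & f[, 3] <= d[3] - 2
    fo <- f[ok, , drop = FALSE]; wo <- w[ok, , drop = FALSE]
    acc <- numeric(sum(ok))
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      wt <- (cx * wo[, 1] + (1 - cx) * (1 - wo[, 1])) *
        (cy * wo[, 2] + (1 - cy) * (1 - wo[, 2])) *
        (cz * wo[, 3] + (1 - cz) * (1 - wo[, 3]))
      idx <- 1 + (fo[, 1] + cx) + d[1] * ((fo[, 2] + cy) + d[2] * (fo[, 3] + cz))
      acc <- acc + wt * volume[idx]
    }
    out[ok] <- acc
  }
  array(out, dim = target_shape)
}

#' Transfer binary masks between grids
#'
#' Nearest-neighbour transfer of segmentation masks (drawn on the structural
#' grid) onto the sodium grid, reporting voxel counts and mm^3 volumes before
#' and after. Empty transferred masks raise an explicit warning (the
#' structure fell outside the field of view).
#'
#' @param masks named list of logical 3D arrays on the source grid.
#' @param source_affine 4x4 affine of the mask grid.
#' @param transform transform mapping target world to source world (or NULL).
#' @param target_shape,target_affine target grid geometry.
#' @return list with `masks` (transferred logical arrays) and `report`
#'   (data.frame: mask, voxels_before, voxels_after, mm3_before, mm3_after).
#' @export
transfer_masks <- function(masks, source_affine, transform, target_shape,
                           target_affine) {
  stopifnot(is.list(masks), length(masks) >= 1)
  vv_src <- abs(det(source_affine[1:3, 1:3]))
  vv_tgt <- abs(det(target_affine[1:3, 1:3]))
  out <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    if (!all(m %in% c(TRUE, FALSE, 0, 1))) stop("mask ", nm, " is not binary")
    t <- resample(m * 1.0, source_affine, transform, target_shape,
                  target_affine, interpolation = "nearest") > 0.5
    if (!any(t))
      warning("mask '", nm, "' is empty after transfer (outside FOV?)")
    t
  })
  names(out) <- names(masks)
  report <- data.frame(
    mask = names(masks),
    voxels_before = vapply(masks, sum, numeric(1)),
    voxels_after = vapply(out, sum, numeric(1)),
    mm3_before = vapply(masks, sum, numeric(1)) * vv_src,
    mm3_after = vapply(out, sum, numeric(1)) * vv_tgt,
    row.names = NULL
  )
  list(masks = out, report = report)
}
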