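#' Round half away from zero
#'
#' Printed tables round ratios and summary means half-up at a fixed number of
#' decimals (unlike R's banker's rounding).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' ROI signal statistics
#'
#' Mean, standard deviation and median of the sodium signal intensity (NaSI)
#' over a masked region, with the mask volume. The median of an even count is
#' the midpoint of the two central values.
#'
#' @param volume numeric 3D array.
#' @param mask logical 3D array, same shape, non-empty.
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param structure,side optional annotations carried into the result.
#' @return object of class `roi_stats` (a one-row data.frame with columns
#'   structure, side, mean, sd, median, voxel_count, volume_mm3).
#' @export
roi_stats <- function(volume, mask, voxel_size_mm = 1,
                      structure = NA_character_, side = NA_character_) {
  stopifnot(all(dim(volume) == dim(mask)))
  if (!any(mask)) stop("empty ROI mask")
  v <- volume[mask]
  out <- data.frame(structure = structure, side = side,
                    mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
                    median = median(v),
                    voxel_count = length(v),
                    volume_mm3 = length(v) * voxel_size_mm^3)
  class(out) <- c("roi_stats", class(out))
  out
}

#' Scale an inner-ear median to the adjacent IAM median
#'
#' The quotient is invariant under any global multiplicative intensity
#' scaling (coil gain), which is the rationale for IAM scaling.
#'
#' @param inner_median median NaSI of the cochlea or vestibule.
#' @param iam_median median NaSI of the adjacent internal auditory meatus
#'   (> 0).
#' @return dimensionless scaled NaSI.
#' @export
scale_to_iam <- function(inner_median, iam_median) {
  if (any(iam_median <= 0)) stop("IAM median must be positive")
  inner_median / iam_median
}

#' Observer-averaged between-ear median ratio
#'
#' Medians are averaged across observers per ear, then the normal:hydropic
#' ratio is formed and rounded half-up to one decimal, matching the printed
#' tables ("calculated from the mean of the two observers").
#'
#' @param normal_medians numeric vector, one median per observer (normal ear).
#' @param hydropic_medians numeric vector, per observer (hydropic ear).
#' @param digits rounding; NULL for the raw ratio.
#' @return ratio (normal:hydropic).
#' @export
between_ear_ratio <- function(normal_medians, hydropic_medians, digits = 1) {
  if (any(normal_medians <= 0) || any(hydropic_medians <= 0))
    stop("medians must be positive")
  r <- mean(normal_medians) / mean(hydropic_medians)
  if (is.null(digits)) r else round_half_up(r, digits)
}

#' Likert assessment of one study by one observer
#'
#' Visibility and anatomical-compatibility grades (0-3) for the IAM, cochlea
#' and vestibule on each side. Grade 0 visibility ("not visible") forces
#' compatibility 0.
#'
#' @param visibility,compatibility named numeric vectors with entries
#'   `iam_right, cochlea_right, vestibule_right, iam_left, cochlea_left,
#'   vestibule_left`, integer grades in 0-3.
#' @param observer,timepoint optional annotations ("pre_registration" /
#'   "post_registration").
#' @return object of class `likert_assessment`.
#' @export
likert_assessment <- function(visibility, compatibility,
                              observer = NA, timepoint = NA) {
  need <- c("iam_right", "cochlea_right", "vestibule_right",
            "iam_left", "cochlea_left", "vestibule_left")
  stopifnot(all(need %in% names(visibility)),
            all(need %in% names(compatibility)))
  visibility <- visibility[need]; compatibility <- compatibility[need]
  if (any(visibility != round(visibility)) || any(visibility < 0) ||
      any(visibility > 3) || any(compatibility != round(compatibility)) ||
      any(compatibility < 0) || any(compatibility > 3))
    stop("grades must be integers in 0-3")
  if (any(visibility == 0 & compatibility != 0))
    stop("visibility 0 ('not visible') requires compatibility 0")
  structure(list(visibility = visibility, compatibility = compatibility,
                 observer = observer, timepoint = timepoint),
            class = "likert_assessment")
}

#' Laterality decision rule from Likert grades
#'
#' For each inner-ear structure s (cochlea, vestibule) and side d, the
#' visibility relative to the ipsilateral IAM fundus is
#' `rel(s,d) = visibility(s,d) - visibility(iam,d)`. Let d+ be the side with
#' the larger rel and `diff(s) = rel(s,d+) - rel(s,d-)`. A structure is
#' eligible if its anatomical compatibility on the better-seen side is at
#' least 2. Among eligible structures the maximum diff decides: >= 2 gives
#' definite laterality, == 1 possible, otherwise none; the hydropic side is
#' the worse-seen side d- of the deciding structure. Eligible structures
#' indicating opposite sides at the same certainty yield none
#' (conservative).
#'
#' @param assessment a [likert_assessment()].
#' @return object of class `laterality_call`: list with `certainty`
#'   ("none", "possible", "definite"), `hydropic_side` ("left"/"right" or
#'   NA), `deciding_structure` ("cochlea"/"vestibule" or NA).
#' @export
classify_laterality <- function(assessment) {
  vis <- assessment$visibility
  comp <- assessment$compatibility
  res <- lapply(c("cochlea", "vestibule"), function(s) {
    rel_r <- vis[[paste0(s, "_right")]] - vis[["iam_right"]]
    rel_l <- vis[[paste0(s, "_left")]] - vis[["iam_left"]]
    if (rel_r >= rel_l) {
      better <- "right"; diff <- rel_r - rel_l
    } else {
      better <- "left"; diff <- rel_l - rel_r
    }
    eligible <- comp[[paste0(s, "_", better)]] >= 2
    list(structure = s, diff = diff, eligible = eligible,
         hydropic = setdiff(c("left", "right"), better))
  })
  res <- Filter(function(r) r$eligible && r$diff >= 1, res)
  if (length(res) == 0)
    return(structure(list(certainty = "none", hydropic_side = NA_character_,
                          deciding_structure = NA_character_),
                     class = "laterality_call"))
  diffs <- vapply(res, function(r) r$diff, numeric(1))
  top <- res[diffs == max(diffs)]
  sides <- unique(vapply(top, function(r) r$hydropic, character(1)))
  if (length(sides) > 1)
    return(structure(list(certainty = "none", hydropic_side = NA_character_,
                          deciding_structure = NA_character_),
                     class = "laterality_call"))
  certainty <- if (max(diffs) >= 2) "definite" else "possible"
  structure(list(certainty = certainty, hydropic_side = sides,
                 deciding_structure = top[[1]]$structure),
            class = "laterality_call")
}

#' Two-way random-effects absolute-agreement ICC
#'
#' Computed from the mean-squares decomposition of the items x raters matrix
#' (rows = items, columns = raters): with MSR (between items), MSC (between
#' raters) and MSE (residual),
#' single measures ICC(A,1) = (MSR - MSE) /
#' (MSR + (k-1) MSE + k (MSC - MSE) / n), and average measures ICC(A,k) =
#' (MSR - MSE) / (MSR + (MSC - MSE) / n).
#'
#' @param ratings numeric matrix, >= 2 rows (items) and >= 2 columns
#'   (raters), no missing cells.
#' @param form "single" or "average".
#' @return the ICC (scalar). A fully degenerate matrix (zero variance
#'   everywhere) returns 1 with a warning.
#' @export
icc_agreement <- function(ratings, form = c("single", "average")) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("missing cells are not supported")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 items and >= 2 raters")
  grand <- mean(ratings)
  if (all(ratings == ratings[1, 1])) {
    warning("degenerate ratings (no variance): ICC = 1 by convention")
    return(1)
  }
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (form == "single")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (msc - mse) / n)
}

#' Cohort summary (demographics table)
#'
#' @param metadata data.frame with columns `participant`, `age_years`, `sex`,
#'   `duration_value`, `duration_unit` ("years"/"months", or "y"/"mo").
#' @return list with mean/range age (years, 1 dp), mean/range symptom
#'   duration (years, months converted before averaging), and sex counts.
#' @export
cohort_summary <- function(metadata) {
  stopifnot(all(c("participant", "age_years", "sex", "duration_value",
                  "duration_unit") %in% names(metadata)))
  unit <- tolower(trimws(metadata$duration_unit))
  fac <- ifelse(unit %in% c("years", "year", "y", "yr"), 1,
                ifelse(unit %in% c("months", "month", "mo", "m"), 1 / 12, NA))
  if (any(is.na(fac)))
    stop("unparseable duration unit in row(s): ",
         paste(which(is.na(fac)), collapse = ", "))
  dur <- metadata$duration_value * fac
  list(
    n = nrow(metadata),
    age_mean = round_half_up(mean(metadata$age_years), 1),
    age_range = range(metadata$age_years),
    duration_mean_years = round_half_up(mean(dur), 1),
    duration_range_years = range(dur),
    sex_counts = table(tolower(substr(metadata$sex, 1, 1)))
  )
}

#' Intensity-threshold segmentation from a seed region
#'
#' Returns the connected component (6-connectivity) of voxels whose intensity
#' exceeds `threshold` times the seed-region mean, restricted to the
#' component containing the seed — the comparable intensity-based
#' thresholding that assists manual inner-ear segmentation.
#'
#' @param volume numeric 3D array (structural contrast).
#' @param seed_mask logical 3D array, non-empty.
#' @param threshold fraction of the seed mean.
#' @return logical 3D array.
#' @export
segment_by_threshold <- function(volume, seed_mask, threshold = 0.5) {
  if (!any(seed_mask)) stop("empty seed region")
  thr <- threshold * mean(volume[seed_mask])
  cand <- volume > thr
  out <- .flood_fill3(as.vector(cand), as.vector(seed_mask), dim(volume))
  out <- array(out, dim = dim(volume))
  if (!any(out)) stop("segmentation is empty: threshold ", signif(thr, 4),
                      " excludes the whole seed region")
  out
}

#' Automatic visibility grade from ROI statistics
#'
#' Grades the visibility of a structure against its adjacent reference
#' structure: 0 if the ROI median is below the reference noise floor
#' (background mean + 2 sd), otherwise 1/2/3 for a ROI:reference median ratio
#' below 0.8 / within 0.8-1.25 / above 1.25 (decreased / similar / increased
#' signal).
#'
#' @param roi_median median NaSI of the graded structure.
#' @param reference_median median NaSI of the adjacent reference structure.
#' @param background_mean,background_sd noise statistics from a signal-free
#'   region.
#' @return integer grade 0-3.
#' @export
grade_visibility_auto <- function(roi_median, reference_median,
                                  background_mean, background_sd) {
  if (reference_median <= 0) stop("degenerate reference statistics")
  if (roi_median < background_mean + 2 * background_sd) return(0L)
  ratio <- roi_median / reference_median
  if (ratio < 0.8) 1L else if (ratio <= 1.25) 2L else 3L
}
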