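test_that("ROI statistics match a sort-based oracle on random masks", {
  expect_equal(roi_stats(array(1:4, c(4, 1, 1)),
                         array(TRUE, c(4, 1, 1)))$median, 2.5)
  expect_equal(roi_stats(array(1:4, c(4, 1, 1)),
                         array(TRUE, c(4, 1, 1)))$mean, 2.5)
  cst <- roi_stats(array(7, c(3, 3, 1)), array(TRUE, c(3, 3, 1)), 2)
  expect_equal(cst$mean, 7); expect_equal(cst$median, 7)
  expect_equal(cst$sd, 0); expect_equal(cst$volume_mm3, 9 * 8)
  set.seed(20)
  v <- array(rnorm(10^3), dim = rep(10, 3))
  for (i in 1:200) {
    m <- array(runif(10^3) < 0.3, dim = rep(10, 3))
    if (!any(m)) next
    r <- roi_stats(v, m)
    s <- sort(v[m]); k <- length(s)
    med_oracle <- if (k %% 2 == 1) s[(k + 1) / 2] else
      (s[k / 2] + s[k / 2 + 1]) / 2
    expect_equal(r$median, med_oracle)
    expect_equal(r$mean, sum(v[m]) / k)
  }
  expect_error(roi_stats(v, array(FALSE, rep(10, 3))), "empty")
})

test_that("IAM scaling is a gain-invariant quotient", {
  expect_equal(scale_to_iam(3.7, 3.7), 1)
  expect_equal(scale_to_iam(6.2, 8.857), scale_to_iam(62, 88.57))
  # back-solved from the printed cochlea row: median 6.2 scaled 0.7
  expect_equal(round_half_up(scale_to_iam(6.2, 8.857), 1), 0.7)
  expect_error(scale_to_iam(1, 0), "positive")
})

test_that("between-ear ratios average observers before the quotient", {
  expect_equal(between_ear_ratio(c(7.9, 10.1), c(6.2, 6.0)), 1.5)
  expect_equal(between_ear_ratio(c(6.4, 5.9), c(7.7, 7.1)), 0.8)
  expect_equal(between_ear_ratio(c(5, 5), c(5, 5)), 1)
  # gain invariance: scaling every median leaves the ratio unchanged
  expect_equal(between_ear_ratio(17 * c(7.9, 10.1), 17 * c(6.2, 6.0)), 1.5)
  expect_error(between_ear_ratio(c(1, -1), c(1, 1)), "positive")
})

test_that("laterality rule reproduces printed calls and handles symmetry", {
  # participant D, post-registration, observer 1: definite left via cochlea
  d1 <- likert_assessment(
    c(iam_right = 1, cochlea_right = 2, vestibule_right = 1,
      iam_left = 1, cochlea_left = 0, vestibule_left = 0),
    c(iam_right = 2, cochlea_right = 2, vestibule_right = 1,
      iam_left = 1, cochlea_left = 0, vestibule_left = 0))
  call <- classify_laterality(d1)
  expect_equal(call$certainty, "definite")
  expect_equal(call$hydropic_side, "left")
  expect_equal(call$deciding_structure, "cochlea")
  # participant C, pre-registration, observer 1: possible left via vestibule
  c1 <- likert_assessment(
    c(iam_right = 1, cochlea_right = 1, vestibule_right = 1,
      iam_left = 1, cochlea_left = 1, vestibule_left = 0),
    c(iam_right = 3, cochlea_right = 3, vestibule_right = 3,
      iam_left = 3, cochlea_left = 1, vestibule_left = 0))
  expect_equal(classify_laterality(c1)$certainty, "possible")
  expect_equal(classify_laterality(c1)$hydropic_side, "left")
  # bilateral symmetric grades give no call
  sym <- likert_assessment(
    setNames(rep(2, 6), names(d1$visibility)),
    setNames(rep(3, 6), names(d1$visibility)))
  expect_equal(classify_laterality(sym)$certainty, "none")
  expect_true(is.na(classify_laterality(sym)$hydropic_side))
  # eligible structures pointing to opposite sides cancel conservatively
  opp <- likert_assessment(
    c(iam_right = 1, cochlea_right = 2, vestibule_right = 1,
      iam_left = 1, cochlea_left = 1, vestibule_left = 2),
    c(iam_right = 2, cochlea_right = 2, vestibule_right = 2,
      iam_left = 2, cochlea_left = 2, vestibule_left = 2))
  expect_equal(classify_laterality(opp)$certainty, "none")
  # the compatibility gate applies on the better-seen side
  gate <- likert_assessment(
    c(iam_right = 1, cochlea_right = 3, vestibule_right = 1,
      iam_left = 1, cochlea_left = 0, vestibule_left = 1),
    c(iam_right = 1, cochlea_right = 1, vestibule_right = 1,
      iam_left = 1, cochlea_left = 0, vestibule_left = 1))
  expect_equal(classify_laterality(gate)$certainty, "none")
  expect_error(likert_assessment(
    c(iam_right = 5, cochlea_right = 0, vestibule_right = 0,
      iam_left = 0, cochlea_left = 0, vestibule_left = 0),
    c(iam_right = 0, cochlea_right = 0, vestibule_right = 0,
      iam_left = 0, cochlea_left = 0, vestibule_left = 0)), "0-3")
})

test_that("ICC equals the ANOVA mean-squares oracle on random matrices", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:20, 1); k <- sample(2:5, 1)
    x <- matrix(rnorm(n * k), n, k) + rnorm(n) + rep(rnorm(k), each = n)
    item <- factor(rep(seq_len(n), k)); rater <- factor(rep(seq_len(k), each = n))
    ms <- summary(aov(as.vector(x) ~ item + rater))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    icc1_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    icck_oracle <- (msr - mse) / (msr + (msc - mse) / n)
    expect_lt(abs(icc_agreement(x, "single") - icc1_oracle), 1e-10)
    expect_lt(abs(icc_agreement(x, "average") - icck_oracle), 1e-10)
  }
})

test_that("ICC edge behaviour: perfect agreement, independence, degeneracy", {
  x <- cbind(1:8, 1:8)
  expect_equal(icc_agreement(x, "single"), 1)
  expect_equal(icc_agreement(x, "average"), 1)
  set.seed(22)
  r <- matrix(rnorm(2000), 1000, 2)
  expect_lt(abs(icc_agreement(r, "single")), 0.1)
  expect_warning(icc_agreement(matrix(3, 4, 2)), "degenerate")
  expect_error(icc_agreement(matrix(1:2, 1, 2)), ">= 2 items")
})

test_that("cohort summary converts months to years before averaging", {
  md <- data.frame(participant = c("A", "B", "C", "D"),
                   age_years = c(78, 62, 68, 33),
                   sex = c("M", "F", "M", "F"),
                   duration_value = c(17, 36, 40, 48),
                   duration_unit = c("years", "months", "years", "months"))
  cs <- cohort_summary(md)
  expect_equal(cs$age_mean, 60.3)
  expect_equal(cs$duration_mean_years, 16)
  expect_equal(as.vector(cs$sex_counts[c("f", "m")]), c(2L, 2L))
  one <- cohort_summary(md[1, ])
  expect_equal(one$age_mean, 78)
  md$duration_unit[2] <- "fortnights"
  expect_error(cohort_summary(md), "row")
})

test_that("threshold segmentation recovers structures and flags empty
           results", {
  v <- array(0.1, dim = rep(12, 3))
  v[4:8, 4:8, 4:8] <- 1
  seed <- array(FALSE, dim = rep(12, 3)); seed[6, 6, 6] <- TRUE
  m <- segment_by_threshold(v, seed, 0.5)
  expect_equal(which(m), which(v == 1))
  expect_error(segment_by_threshold(v, seed, 1.01), "empty")
  expect_error(segment_by_threshold(v, seed & FALSE), "empty seed")
  # phantom cochlea segmented from the structural contrast lands in the
  # printed 63-110 mm^3 observer range
  ph <- build_phantom(phantom_spec())
  sv <- phantom_structural(ph)
  cseed <- ph$masks$cochlea_right
  seg <- segment_by_threshold(sv, cseed, 0.6)
  # restrict to the cochlear neighbourhood (threshold also admits other
  # connected fluid); the segmentation must cover the cochlea itself
  expect_true(all(seg[cseed]))
  vol <- sum(seg & cseed) * ph$voxel_size_mm^3
  expect_gte(vol, 63); expect_lte(vol, 110)
})

test_that("automatic visibility grading follows the Likert bands", {
  expect_equal(grade_visibility_auto(5, 5, 0, 0.1), 2L)
  expect_equal(grade_visibility_auto(3.9, 5, 0, 0.1), 1L)
  expect_equal(grade_visibility_auto(6.5, 5, 0, 0.1), 3L)
  expect_equal(grade_visibility_auto(0.1, 5, 0.5, 0.5), 0L)
  expect_error(grade_visibility_auto(1, 0, 0, 0), "degenerate")
})

test_that("half-up rounding matches the printed tables' convention", {
  expect_equal(round_half_up(60.25, 1), 60.3)
  expect_equal(round_half_up(1.45, 1), 1.5)
  expect_equal(round_half_up(-1.45, 1), -1.5)
  expect_equal(round_half_up(0.84999, 1), 0.8)
})
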