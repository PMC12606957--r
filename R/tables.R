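#' Read a Likert grade table
#'
#' Delimited text with one row per (participant, timepoint, observer) and
#' visibility/compatibility columns `vis_<structure>_<side>` /
#' `comp_<structure>_<side>` for the IAM, cochlea and vestibule on each side.
#' The bundled fixture `likert_grades.csv` transcribes the study's qualitative
#' analysis table (including the printed certainty/side columns for
#' cross-checking).
#'
#' @param path CSV path; default the bundled fixture.
#' @return data.frame with an `assessment` list-column of
#'   [likert_assessment()] objects.
#' @export
read_grade_table <- function(path = system.file("extdata",
                                                "likert_grades.csv",
                                                package = "sodiumear")) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "timepoint", "observer")
  stopifnot(all(need %in% names(d)))
  structures <- c("iam_right", "cochlea_right", "vestibule_right",
                  "iam_left", "cochlea_left", "vestibule_left")
  d$assessment <- lapply(seq_len(nrow(d)), function(i) {
    vis <- setNames(as.numeric(d[i, paste0("vis_", structures)]), structures)
    comp <- setNames(as.numeric(d[i, paste0("comp_", structures)]), structures)
    likert_assessment(vis, comp, observer = d$observer[i],
                      timepoint = d$timepoint[i])
  })
  d
}

#' Apply the laterality rule to a grade table
#'
#' @param grades a [read_grade_table()] result.
#' @return the input with `certainty`, `hydropic_side` and
#'   `deciding_structure` columns appended.
#' @export
classify_grade_table <- function(grades) {
  calls <- lapply(grades$assessment, classify_laterality)
  grades$certainty <- vapply(calls, function(c) c$certainty, character(1))
  grades$hydropic_side <- vapply(calls, function(c) c$hydropic_side,
                                 character(1))
  grades$deciding_structure <- vapply(calls, function(c) c$deciding_structure,
                                      character(1))
  grades
}

#' Count participants lateralised by both observers
#'
#' A participant counts when, at the given timepoint, both observers' calls
#' are non-none; `wrong_side` additionally reports calls on the wrong side
#' relative to the known disease laterality (when supplied).
#'
#' @param classified a [classify_grade_table()] result.
#' @param timepoint "pre_registration" or "post_registration".
#' @param true_side optional named character vector of disease laterality per
#'   participant.
#' @return list with `n_both`, `participants`, and `n_wrong_side`.
#' @export
count_lateralised <- function(classified, timepoint, true_side = NULL) {
  d <- classified[classified$timepoint == timepoint, ]
  sp <- split(d, d$participant)
  both <- vapply(sp, function(g) all(g$certainty != "none"), logical(1))
  wrong <- 0L
  if (!is.null(true_side)) {
    called <- d[d$certainty != "none", ]
    wrong <- sum(called$hydropic_side != true_side[called$participant])
  }
  list(n_both = sum(both), participants = names(both)[both],
       n_wrong_side = wrong)
}

#' Read an ROI median table (printed layout)
#'
#' One row per (participant, observer) with mean/sd/median and IAM-scaled
#' median for the hydropic (`eh_*`) and normal (`normal_*`) ear. Bundled
#' fixtures: `roi_medians_cochlea.csv`, `roi_medians_vestibule.csv`.
#'
#' @param structure "cochlea" or "vestibule" (selects the bundled fixture),
#'   ignored when `path` is given.
#' @param path optional CSV path.
#' @return data.frame.
#' @export
read_median_table <- function(structure = c("cochlea", "vestibule"),
                              path = NULL) {
  if (is.null(path)) {
    structure <- match.arg(structure)
    path <- system.file("extdata",
                        paste0("roi_medians_", structure, ".csv"),
                        package = "sodiumear")
  }
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "observer", "eh_median", "normal_median")
  stopifnot(all(need %in% names(d)))
  d
}

#' Between-ear ratio report from a median table
#'
#' Reproduces the printed quantitative layout: per participant, the
#' per-observer medians for both ears, the observer-averaged medians, the
#' normal:hydropic ratio (1 dp, half-up), and the same from the IAM-scaled
#' medians when scaled columns are present.
#'
#' @param medians a [read_median_table()] result.
#' @return data.frame, one row per participant.
#' @export
ratio_report <- function(medians) {
  sp <- split(medians, medians$participant)
  rows <- lapply(sp, function(g) {
    g <- g[order(g$observer), ]
    out <- data.frame(
      participant = g$participant[1],
      eh_median_obs1 = g$eh_median[1], eh_median_obs2 = g$eh_median[2],
      normal_median_obs1 = g$normal_median[1],
      normal_median_obs2 = g$normal_median[2],
      eh_median_avg = mean(g$eh_median),
      normal_median_avg = mean(g$normal_median),
      ratio = between_ear_ratio(g$normal_median, g$eh_median)
    )
    if (all(c("eh_scaled", "normal_scaled") %in% names(g))) {
      out$scaled_ratio <- between_ear_ratio(g$normal_scaled, g$eh_scaled)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read cohort metadata
#'
#' @param path CSV path; default the bundled demographics fixture.
#' @return data.frame suitable for [cohort_summary()].
#' @export
read_cohort_table <- function(path = system.file("extdata",
                                                 "cohort_metadata.csv",
                                                 package = "sodiumear")) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Inner-ear median matrix for inter-observer agreement
#'
#' Stacks the cochlea and vestibule median tables into the items x raters
#' matrix used for the ICC: one row per (participant, structure, ear), one
#' column per observer.
#'
#' @param cochlea,vestibule [read_median_table()] results.
#' @return numeric matrix with 2 columns.
#' @export
median_rating_matrix <- function(cochlea = read_median_table("cochlea"),
                                 vestibule = read_median_table("vestibule")) {
  stack_one <- function(d, structure) {
    w <- merge(d[d$observer == 1, c("participant", "eh_median", "normal_median")],
               d[d$observer == 2, c("participant", "eh_median", "normal_median")],
               by = "participant", suffixes = c("_1", "_2"))
    rbind(
      matrix(c(w$eh_median_1, w$eh_median_2), ncol = 2,
             dimnames = list(paste(structure, w$participant, "eh"), NULL)),
      matrix(c(w$normal_median_1, w$normal_median_2), ncol = 2,
             dimnames = list(paste(structure, w$participant, "normal"), NULL))
    )
  }
  rbind(stack_one(cochlea, "cochlea"), stack_one(vestibule, "vestibule"))
}
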