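# Trial- and condition-level dependent variables.

#' Per-trial looking totals by AOI
#'
#' Sums fixation durations toward the upper and lower face halves for each
#' kept trial and derives the trial-level lower-half proportion. Fixations
#' labelled `"none"` contribute to neither total.
#'
#' @param fixations Labeled fixation tibble ([label_fixations()]), ideally
#'   already restricted to kept trials with [exclude_trials()].
#' @return Tibble with one row per trial: `subject_id`, `trial_number`,
#'   stimulus columns, `looking_upper`, `looking_lower` (ms), and
#'   `proportion_lower` (`NA` when no fixation landed in either half).
#' @export
trial_totals <- function(fixations) {
  check_columns(fixations, c("subject_id", "trial_number", "duration_ms",
                             "aoi"), "fixations")
  id_cols <- intersect(
    c("subject_id", "trial_number", "stimulus_id", "face_race", "speech_type"),
    names(fixations)
  )
  fixations %>%
    group_by(dplyr::across(dplyr::all_of(id_cols))) %>%
    summarise(
      looking_upper = sum(.data$duration_ms[.data$aoi == "upper"]),
      looking_lower = sum(.data$duration_ms[.data$aoi == "lower"]),
      .groups = "drop"
    ) %>%
    mutate(
      proportion_lower = dplyr::if_else(
        .data$looking_upper + .data$looking_lower > 0,
        .data$looking_lower / (.data$looking_lower + .data$looking_upper),
        NA_real_
      )
    )
}

#' Condition-level lower-half preference per subject
#'
#' Aggregates a subject's trials within each stimulus condition. The
#' default pools by duration (`sum(lower) / sum(lower + upper)` across the
#' condition's trials), which weights trials by how much the infant looked;
#' `method = "mean"` instead averages the per-trial proportions. Subjects
#' missing any of the conditions are flagged `complete = FALSE` (a
#' four-condition repeated-measures analysis needs all four).
#'
#' @param trial_dvs Output of [trial_totals()].
#' @param method `"pooled"` (default) or `"mean"`.
#' @param n_conditions Number of stimulus conditions in the design a
#'   subject must cover to count as complete (default 4).
#' @return Tibble: `subject_id`, `face_race`, `speech_type`,
#'   `n_trials`, `proportion_lower`, `complete`.
#' @export
condition_preference <- function(trial_dvs, method = c("pooled", "mean"),
                                 n_conditions = 4) {
  method <- match.arg(method)
  check_columns(trial_dvs, c("subject_id", "face_race", "speech_type",
                             "looking_upper", "looking_lower"), "trial_dvs")
  out <- trial_dvs %>%
    group_by(.data$subject_id, .data$face_race, .data$speech_type) %>%
    summarise(
      n_trials = dplyr::n(),
      proportion_lower = if (method == "pooled") {
        sum(.data$looking_lower) /
          (sum(.data$looking_lower) + sum(.data$looking_upper))
      } else {
        mean(.data$proportion_lower, na.rm = TRUE)
      },
      .groups = "drop"
    )
  out %>%
    group_by(.data$subject_id) %>%
    mutate(complete = dplyr::n() == n_conditions) %>%
    ungroup()
}

#' Long fixation table for mixed-model analyses
#'
#' One row per fixation on a kept trial, carrying the within-trial fixation
#' index, trial and condition identifiers, AOI label, and subject
#' covariates — the input table consumed by downstream (out-of-package)
#' mixed-effects fits of fixation duration and fixation location.
#'
#' @param fixations Labeled fixations restricted to kept trials.
#' @param subjects Subject covariate tibble (e.g. `simulate_session()$subjects`
#'   or the output of [classify_subjects()]); joined by `subject_id`.
#' @return Tibble with one row per fixation.
#' @export
fixation_table <- function(fixations, subjects = NULL) {
  check_columns(fixations, c("subject_id", "trial_number", "fixation_index",
                             "duration_ms", "aoi"), "fixations")
  out <- arrange(fixations, .data$subject_id, .data$trial_number,
                 .data$fixation_index)
  if (!is.null(subjects)) {
    out <- left_join(out, subjects, by = "subject_id")
  }
  out
}
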