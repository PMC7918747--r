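# 250 ms binned time courses of the lower-half preference.

#' Time-bin configuration
#'
#' Defaults follow the analysis design: 250 ms bins of 30 raw samples
#' (8.33 ms each at 120 Hz) over the first 7500 ms of each trial, giving
#' exactly 30 bins; chance is 0.50 (equal looking to the two halves).
#'
#' @param bin_width Bin width in ms (default 250).
#' @param analysis_window Length of trial analysed, ms (default 7500); must
#'   be an exact multiple of `bin_width`.
#' @param sample_rate Sampling rate in Hz, used to derive samples per bin
#'   (default 120).
#' @param chance Chance proportion (default 0.5).
#' @return List of class `bin_config` with fields `bin_width`,
#'   `analysis_window`, `n_bins`, `samples_per_bin`, `chance`.
#' @export
bin_config <- function(bin_width = 250, analysis_window = 7500,
                       sample_rate = 120, chance = 0.5) {
  check_positive(bin_width, "bin_width")
  check_positive(analysis_window, "analysis_window")
  check_prob(chance, "chance")
  if (analysis_window %% bin_width != 0) {
    config_error("`analysis_window` must be an exact multiple of `bin_width`.")
  }
  structure(
    list(
      bin_width = bin_width,
      analysis_window = analysis_window,
      n_bins = as.integer(analysis_window / bin_width),
      samples_per_bin = bin_width * sample_rate / 1000,
      chance = chance
    ),
    class = "bin_config"
  )
}

#' Bin labeled samples into per-trial time courses
#'
#' Divides the first `analysis_window` ms of each trial into half-open
#' `[k * bin_width, (k + 1) * bin_width)` bins (indexed from 0) and counts
#' the AOI-labeled samples in each: `n_lower`, `n_upper`, and `n_none`
#' (everything else, including track loss). The per-bin proportion toward
#' the lower half is `n_lower / (n_lower + n_upper)` — the number of
#' samples in the lower half over all samples in either half — and is
#' missing when no sample was in either half.
#'
#' @param labeled_samples Output of [label_samples()].
#' @param cfg A [bin_config()].
#' @return Tibble with one row per trial x bin: identifying columns,
#'   `bin_index`, `bin_onset_ms`, `bin_offset_ms`, `n_lower`, `n_upper`,
#'   `n_none`, `n_samples`, `proportion_lower`.
#' @export
#' @examples
#' # a bin with 12 lower and 18 upper samples has proportion 12/30 = 0.40
bin_trials <- function(labeled_samples, cfg = bin_config()) {
  check_columns(labeled_samples, c("subject_id", "trial_number", "time_ms",
                                   "aoi"), "labeled_samples")
  id_cols <- intersect(
    c("subject_id", "trial_number", "stimulus_id", "face_race", "speech_type"),
    names(labeled_samples)
  )
  bins <- tibble(bin_index = 0:(cfg$n_bins - 1L))
  labeled_samples %>%
    filter(.data$time_ms < cfg$analysis_window) %>%
    mutate(bin_index = as.integer(.data$time_ms %/% cfg$bin_width)) %>%
    group_by(dplyr::across(dplyr::all_of(c(id_cols, "bin_index")))) %>%
    summarise(
      n_lower = sum(.data$aoi == "lower", na.rm = TRUE),
      n_upper = sum(.data$aoi == "upper", na.rm = TRUE),
      n_samples = dplyr::n(),
      .groups = "drop"
    ) %>%
    # every trial gets all n_bins bins, even if it has no samples there
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(id_cols)), bins,
      fill = list(n_lower = 0L, n_upper = 0L, n_samples = 0L)
    ) %>%
    mutate(
      n_none = .data$n_samples - .data$n_lower - .data$n_upper,
      bin_onset_ms = .data$bin_index * cfg$bin_width,
      bin_offset_ms = (.data$bin_index + 1) * cfg$bin_width,
      proportion_lower = dplyr::if_else(
        .data$n_lower + .data$n_upper > 0,
        .data$n_lower / (.data$n_lower + .data$n_upper),
        NA_real_
      )
    ) %>%
    select(dplyr::all_of(id_cols), "bin_index", "bin_onset_ms",
           "bin_offset_ms", "n_lower", "n_upper", "n_none", "n_samples",
           "proportion_lower") %>%
    arrange(dplyr::across(dplyr::all_of(c(id_cols, "bin_index"))))
}

#' Per-subject mean time courses
#'
#' Averages each subject's per-trial bin proportions, bin by bin, either
#' across all trials (`by_condition = FALSE`) or separately within each
#' stimulus condition. Averaging is available-case: a trial missing a bin
#' simply does not contribute there, and a subject's bin is missing only
#' when it is missing in every contributing trial. No imputation.
#'
#' @param trial_tc Output of [bin_trials()].
#' @param by_condition Average within face race x speech type instead of
#'   across all trials.
#' @return Tibble: `subject_id`, (`face_race`, `speech_type`,) `bin_index`,
#'   `bin_onset_ms`, `bin_offset_ms`, `n_trials`, `proportion_lower`.
#' @export
subject_timecourse <- function(trial_tc, by_condition = FALSE) {
  check_columns(trial_tc, c("subject_id", "bin_index", "proportion_lower"),
                "trial_tc")
  grp <- c("subject_id",
           if (by_condition) c("face_race", "speech_type"),
           "bin_index", "bin_onset_ms", "bin_offset_ms")
  trial_tc %>%
    group_by(dplyr::across(dplyr::all_of(grp))) %>%
    summarise(
      n_trials = sum(!is.na(.data$proportion_lower)),
      proportion_lower = if (all(is.na(.data$proportion_lower))) NA_real_
                         else mean(.data$proportion_lower, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Subject-weighted group time course
#'
#' Averages subject time courses bin by bin, weighting each subject equally
#' regardless of trial count, with the per-bin number of contributing
#' subjects and a t-based 95% confidence interval.
#'
#' @param subject_tc Output of [subject_timecourse()]; if it carries
#'   `face_race`/`speech_type` columns the group time course is computed per
#'   condition.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return Tibble: (condition columns,) `bin_index`, `bin_onset_ms`,
#'   `bin_offset_ms`, `n_subjects`, `proportion_lower`, `ci_lower`,
#'   `ci_upper`.
#' @export
group_timecourse <- function(subject_tc, conf_level = 0.95) {
  check_columns(subject_tc, c("subject_id", "bin_index", "proportion_lower"),
                "subject_tc")
  grp <- c(intersect(c("face_race", "speech_type"), names(subject_tc)),
           "bin_index", "bin_onset_ms", "bin_offset_ms")
  subject_tc %>%
    group_by(dplyr::across(dplyr::all_of(grp))) %>%
    summarise(
      n_subjects = sum(!is.na(.data$proportion_lower)),
      mean_p = if (all(is.na(.data$proportion_lower))) NA_real_
               else mean(.data$proportion_lower, na.rm = TRUE),
      se = stats::sd(.data$proportion_lower, na.rm = TRUE) /
        sqrt(pmax(sum(!is.na(.data$proportion_lower)), 1)),
      .groups = "drop"
    ) %>%
    mutate(
      tcrit = dplyr::if_else(.data$n_subjects >= 2,
                             qt(1 - (1 - conf_level) / 2,
                                .data$n_subjects - 1),
                             NA_real_),
      ci_lower = .data$mean_p - .data$tcrit * .data$se,
      ci_upper = .data$mean_p + .data$tcrit * .data$se
    ) %>%
    rename(proportion_lower = "mean_p") %>%
    select(-"tcrit", -"se")
}
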