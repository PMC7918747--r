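# Dynamic AOI assignment for samples and fixations, and trial exclusion.

# Step-function lookup of the AOI rectangles at arbitrary times: for each
# query time use the trajectory row with the largest time_ms <= t.
aoi_lookup <- function(aoi_one_region, t) {
  idx <- findInterval(t, aoi_one_region$time_ms)
  if (any(idx == 0)) {
    data_error("AOI trajectory does not cover every sample timestamp.")
  }
  aoi_one_region[idx, c("x_min", "y_min", "x_max", "y_max")]
}

#' Assign gaze samples to dynamic face-half AOIs
#'
#' Labels each valid sample `"upper"`, `"lower"`, or `"none"` by a
#' point-in-rectangle test against the AOI positions at that sample's
#' timestamp, so the same screen point can be labelled differently as the
#' face moves. Rectangles are half-open (`x_min <= x < x_max`,
#' `y_min <= y < y_max`) except that the shared horizontal edge between the
#' halves belongs to the upper AOI. Invalid samples get `NA`.
#'
#' @param samples Raw sample tibble (see [simulate_session()]); must carry
#'   `stimulus_id` matching the trajectory table.
#' @param aoi AOI trajectory tibble (see [make_aoi_trajectory()]).
#' @return `samples` with an added character column `aoi`.
#' @export
label_samples <- function(samples, aoi) {
  check_columns(samples, c("stimulus_id", "time_ms", "x_px", "y_px", "valid"),
                "samples")
  check_columns(aoi, c("stimulus_id", "time_ms", "region",
                       "x_min", "y_min", "x_max", "y_max"), "aoi")
  samples %>%
    group_by(.data$stimulus_id) %>%
    dplyr::group_modify(function(df, key) {
      stim_aoi <- filter(aoi, .data$stimulus_id == key$stimulus_id)
      if (nrow(stim_aoi) == 0) {
        data_error(sprintf("No AOI trajectory for stimulus '%s'.",
                           key$stimulus_id))
      }
      up <- arrange(filter(stim_aoi, .data$region == "upper"), .data$time_ms)
      lo <- arrange(filter(stim_aoi, .data$region == "lower"), .data$time_ms)
      ru <- aoi_lookup(up, df$time_ms)
      rl <- aoi_lookup(lo, df$time_ms)
      x <- df$x_px; y <- df$y_px
      # Upper tested first with an inclusive bottom edge, so the shared
      # boundary belongs to the upper half and the halves still partition.
      in_up <- x >= ru$x_min & x < ru$x_max & y >= ru$y_min & y <= ru$y_max
      in_lo <- x >= rl$x_min & x < rl$x_max & y >= rl$y_min & y < rl$y_max
      lab <- dplyr::case_when(
        df$valid != 1 | is.na(x) | is.na(y) ~ NA_character_,
        in_up ~ "upper",
        in_lo ~ "lower",
        TRUE ~ "none"
      )
      mutate(df, aoi = lab)
    }) %>%
    ungroup() %>%
    select(dplyr::all_of(names(samples)), "aoi")
}

#' Assign one sample to an AOI
#'
#' Scalar convenience wrapper around the same rule as [label_samples()].
#'
#' @param x,y Gaze coordinates in px.
#' @param upper,lower Numeric vectors `c(x_min, y_min, x_max, y_max)` giving
#'   the two rectangles at the sample's timestamp.
#' @return `"upper"`, `"lower"`, or `"none"`.
#' @export
#' @examples
#' assign_sample_aoi(100, 150, upper = c(0, 0, 200, 100),
#'                   lower = c(0, 100, 200, 200))
assign_sample_aoi <- function(x, y, upper, lower) {
  if (x >= upper[1] && x < upper[3] && y >= upper[2] && y <= upper[4]) {
    "upper"
  } else if (x >= lower[1] && x < lower[3] && y >= lower[2] && y < lower[4]) {
    "lower"
  } else {
    "none"
  }
}

#' Assign fixations to AOIs by majority of member samples
#'
#' A fixation's AOI is the majority label among its member samples'
#' per-sample AOI labels. An upper/lower tie takes the label of the
#' temporally first member sample that is in an AOI; if no member sample is
#' in an AOI (or `"none"` has the strict plurality) the fixation is labelled
#' `"none"`.
#'
#' @param fixations Output of [detect_fixations()].
#' @param labeled_samples Output of [label_samples()].
#' @return `fixations` with an added character column `aoi`.
#' @export
label_fixations <- function(fixations, labeled_samples) {
  check_columns(labeled_samples, c("subject_id", "trial_number", "time_ms",
                                   "aoi"), "labeled_samples")
  check_columns(fixations, c("subject_id", "trial_number", "start_ms",
                             "end_ms"), "fixations")
  fixations %>%
    group_by(.data$subject_id, .data$trial_number) %>%
    dplyr::group_modify(function(fx, key) {
      smp <- labeled_samples %>%
        filter(.data$subject_id == key$subject_id,
               .data$trial_number == key$trial_number) %>%
        arrange(.data$time_ms)
      # tolerance guards against 1-ulp drift between k*period and
      # cumulative-sum timestamps at the window edges
      eps <- 1e-6
      fx$aoi <- purrr::map2_chr(fx$start_ms, fx$end_ms, function(a, b) {
        labs <- smp$aoi[smp$time_ms >= a - eps & smp$time_ms < b - eps]
        labs <- labs[!is.na(labs)]
        majority_aoi(labs)
      })
      fx
    }) %>%
    ungroup()
}

majority_aoi <- function(labs) {
  n_up <- sum(labs == "upper")
  n_lo <- sum(labs == "lower")
  n_no <- sum(labs == "none")
  if (n_up + n_lo == 0) return("none")
  if (n_no > n_up && n_no > n_lo) return("none")
  if (n_up > n_lo) return("upper")
  if (n_lo > n_up) return("lower")
  # upper/lower tie: first member sample that is in an AOI decides
  labs[labs != "none"][1]
}

#' Trial inclusion by total recorded looking
#'
#' A trial is kept when its summed fixation duration reaches
#' `min_trial_looking` ms (inclusive: exactly 1000 ms is kept at the
#' default). "Recorded looking" is fixation time, the pipeline's unit of
#' looking; the threshold is configurable via [detector_config()].
#'
#' @param fixations Fixation tibble with `subject_id`, `trial_number`,
#'   `duration_ms`.
#' @param cfg A [detector_config()].
#' @return Tibble with one row per trial: identifying columns,
#'   `total_looking_ms`, and logical `keep`.
#' @export
apply_trial_exclusion <- function(fixations, cfg = detector_config()) {
  check_columns(fixations, c("subject_id", "trial_number", "duration_ms"),
                "fixations")
  fixations %>%
    group_by(.data$subject_id, .data$trial_number) %>%
    summarise(total_looking_ms = sum(.data$duration_ms), .groups = "drop") %>%
    mutate(keep = .data$total_looking_ms >= cfg$min_trial_looking)
}

#' Drop excluded trials from a fixation or sample table
#'
#' @param x Tibble with `subject_id` and `trial_number`.
#' @param inclusion Output of [apply_trial_exclusion()].
#' @return `x` restricted to kept trials.
#' @export
exclude_trials <- function(x, inclusion) {
  keep <- filter(inclusion, .data$keep)
  dplyr::semi_join(x, keep, by = c("subject_id", "trial_number"))
}
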