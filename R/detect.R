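# Dispersion-threshold (I-DT) fixation identification.

#' Fixation detector configuration
#'
#' @param min_duration Minimum fixation duration in ms (default 80).
#' @param max_dispersion Maximum dispersion in px (default 100); dispersion
#'   is `(max x - min x) + (max y - min y)` over the window, the classic
#'   I-DT sum.
#' @param min_trial_looking Minimum total fixation time (ms) for a trial to
#'   be kept (default 1000, inclusive).
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(min_duration = 80,
                            max_dispersion = 100,
                            min_trial_looking = 1000) {
  check_positive(min_duration, "min_duration")
  check_positive(max_dispersion, "max_dispersion")
  check_positive(min_trial_looking, "min_trial_looking")
  structure(
    list(
      min_duration = min_duration,
      max_dispersion = max_dispersion,
      min_trial_looking = min_trial_looking
    ),
    class = "detector_config"
  )
}

#' Gaze dispersion of a sample window
#'
#' The I-DT dispersion metric: `(max x - min x) + (max y - min y)`.
#'
#' @param x,y Coordinates in px of the samples in the window.
#' @return Dispersion in px.
#' @export
#' @examples
#' gaze_dispersion(c(0, 30), c(0, 40)) # 70
gaze_dispersion <- function(x, y) {
  if (length(x) == 0) data_error("Dispersion of an empty window is undefined.")
  (max(x) - min(x)) + (max(y) - min(y))
}

# I-DT on one uninterrupted run of valid samples (compiled scan in
# src/idt.cpp). Duration counts one sample period per sample
# (n * period), so 60 samples at 120 Hz = 500 ms.
idt_run <- function(x, y, min_samples, max_dispersion) {
  idt_run_cpp(x, y, as.integer(min_samples), max_dispersion)
}

# Detect fixations in the samples of a single trial (already time-ordered).
detect_fixations_trial <- function(time_ms, x_px, y_px, valid, cfg) {
  if (is.unsorted(time_ms, strictly = TRUE)) {
    data_error("Sample timestamps must be strictly increasing within a trial.")
  }
  empty <- tibble(fixation_index = integer(0), start_ms = numeric(0),
                  end_ms = numeric(0), duration_ms = numeric(0),
                  centroid_x = numeric(0), centroid_y = numeric(0),
                  n_samples = integer(0))
  n <- length(time_ms)
  if (n == 0) return(empty)
  period <- if (n > 1) median(diff(time_ms)) else 1000 / 120
  min_samples <- max(1L, as.integer(ceiling(cfg$min_duration / period)))

  # Invalid samples break candidate windows: run I-DT within each maximal
  # run of consecutive valid samples.
  ok <- valid == 1 & !is.na(x_px) & !is.na(y_px)
  runs <- rle(ok)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  s_idx <- e_idx <- integer(0)
  for (ri in which(runs$values & runs$lengths >= min_samples)) {
    a <- run_start[ri]
    b <- run_end[ri]
    res <- idt_run(x_px[a:b], y_px[a:b], min_samples, cfg$max_dispersion)
    if (length(res$start) > 0) {
      s_idx <- c(s_idx, res$start + a - 1L)
      e_idx <- c(e_idx, res$end + a - 1L)
    }
  }
  if (length(s_idx) == 0) return(empty)

  # centroids from cumulative sums (windows never include invalid samples)
  cumx <- cumsum(ifelse(ok, x_px, 0))
  cumy <- cumsum(ifelse(ok, y_px, 0))
  left_x <- ifelse(s_idx > 1, cumx[pmax(s_idx - 1L, 1L)], 0)
  left_y <- ifelse(s_idx > 1, cumy[pmax(s_idx - 1L, 1L)], 0)
  len <- e_idx - s_idx + 1L
  tibble(
    fixation_index = seq_along(s_idx),
    start_ms = time_ms[s_idx],
    end_ms = time_ms[e_idx] + period,
    duration_ms = time_ms[e_idx] + period - time_ms[s_idx],
    centroid_x = (cumx[e_idx] - left_x) / len,
    centroid_y = (cumy[e_idx] - left_y) / len,
    n_samples = len
  )
}

#' Detect fixations with a dispersion-threshold (I-DT) filter
#'
#' Identifies fixations as maximal windows of consecutive valid samples
#' whose dispersion (`(max x - min x) + (max y - min y)`) stays at or below
#' `max_dispersion` and whose duration is at least `min_duration`. A
#' sample's duration contribution is one sample period, so a window of k
#' samples lasts `k * period` ms. Invalid (track-lost) samples break
#' candidate windows; there is no gap bridging.
#'
#' @param samples Tibble of gaze samples with columns `subject_id`,
#'   `trial_number`, `time_ms`, `x_px`, `y_px`, `valid`, plus any stimulus
#'   columns (carried through). May contain many trials; detection is per
#'   trial.
#' @param cfg A [detector_config()].
#' @return Tibble of fixations: identifying columns, `fixation_index`
#'   (1-based within trial), `start_ms`, `end_ms` (exclusive: last sample
#'   time + period), `duration_ms`, `centroid_x`, `centroid_y`, `n_samples`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 1, trials_per_subject = 1, seed = 7)
#' sess <- simulate_session(cfg)
#' fx <- detect_fixations(sess$samples, detector_config())
#' head(fx)
detect_fixations <- function(samples, cfg = detector_config()) {
  check_columns(samples,
                c("subject_id", "trial_number", "time_ms", "x_px", "y_px",
                  "valid"),
                "samples")
  id_cols <- intersect(
    c("subject_id", "trial_number", "stimulus_id", "face_race", "speech_type"),
    names(samples)
  )
  samples %>%
    group_by(dplyr::across(dplyr::all_of(id_cols))) %>%
    arrange(.data$time_ms, .by_group = TRUE) %>%
    dplyr::group_modify(~ detect_fixations_trial(
      .x$time_ms, .x$x_px, .x$y_px, .x$valid, cfg
    )) %>%
    ungroup()
}
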