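#' Simulation configuration for synthetic eye-tracking sessions
#'
#' Bundles every parameter of the synthetic-session generator: cohort size
#' and trial structure, eye-tracker sampling, fixation/saccade dynamics,
#' track loss, stimulus face motion, and the time-varying probability that
#' a fixation targets the lower half of the face.
#'
#' The defaults reproduce the acquisition design the pipeline is built for:
#' 120 Hz sampling, 7500 ms trials, up to 8 trials per infant (two per
#' stimulus type across face race \{Asian American, White\} x speech type
#' \{infant-directed, adult-directed\}), on a 1680 x 1050 px screen.
#'
#' Screen geometry uses a pinned conversion of 35 px/cm (a 22-inch 16:10
#' panel at 1680 x 1050); the two stacked face-half AOIs are each 16 cm wide
#' by 8.5 cm high at that scale. The conversion constant is a package choice
#' exposed via `px_per_cm` because only physical AOI sizes are specified.
#'
#' @param n_subjects Number of infants to simulate.
#' @param trials_per_subject Trials per infant (default 8, two per stimulus
#'   type; must not exceed `2 * n_stimulus_types`).
#' @param n_stimulus_types Number of stimulus conditions (default 4).
#' @param sample_rate Eye-tracker sampling rate in Hz (default 120).
#' @param trial_duration Trial length in ms (default 7500).
#' @param fixation_duration_mean,fixation_duration_sd Mean and SD (ms) of
#'   simulated fixation durations (normal, truncated below at
#'   `fixation_duration_min`).
#' @param fixation_duration_min Shortest planted fixation in ms (default 100,
#'   above the 80 ms detector minimum so planted fixations are detectable).
#' @param saccade_gap Gap between consecutive fixations in ms (default 40,
#'   rounded to whole sample periods; well under the 80 ms minimum so
#'   saccades never register as fixations).
#' @param trackloss_rate Per-sample probability that the tracker loses the
#'   eye (sample flagged invalid).
#' @param bias_profile Tibble describing the probability that a fixation
#'   targets the lower AOI as a function of condition and trial time; see
#'   [bias_profile()]. Default: constant 0.5 (no preference).
#' @param face_motion_amplitude Amplitude in px of the smooth planar motion
#'   of the stimulus face (default 20).
#' @param fixation_jitter_sd Isotropic within-fixation gaze jitter SD in px
#'   (default 4). The detector's dispersion metric is the sum of the x and y
#'   ranges; the range of a cloud of ~100 jittered samples is about five
#'   per-axis SDs, and gaze tracks the moving face, so jitter spread plus
#'   worst-case motion drift must stay below the 100 px cap.
#' @param min_saccade_px Minimum distance in px between consecutive planted
#'   fixation targets (default 250). Together with mid-flight saccade
#'   sampling this keeps every saccade sample at least one dispersion cap
#'   away from both fixation clouds, so saccades neither register as
#'   fixations nor blur adjacent fixations together.
#' @param screen_width,screen_height Screen size in px (default 1680 x 1050).
#' @param px_per_cm Pixels per centimetre used to size the AOIs (default 35).
#' @param aoi_width_cm,aoi_half_height_cm Physical AOI size: each half is
#'   `aoi_width_cm` wide and `aoi_half_height_cm` high (defaults 16 and 8.5).
#' @param seed Master seed; every (subject, trial) draws from its own stream
#'   derived from this value, so identical seed + config gives bit-identical
#'   output.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_session()], [bias_profile()], [inject_bias()]
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 4, seed = 1)
#' cfg$trial_duration / 1000 * cfg$sample_rate  # samples per trial
sim_config <- function(n_subjects = 10,
                       trials_per_subject = 8,
                       n_stimulus_types = 4,
                       sample_rate = 120,
                       trial_duration = 7500,
                       fixation_duration_mean = 400,
                       fixation_duration_sd = 150,
                       fixation_duration_min = 100,
                       saccade_gap = 40,
                       trackloss_rate = 0.05,
                       bias_profile = NULL,
                       face_motion_amplitude = 20,
                       fixation_jitter_sd = 4,
                       min_saccade_px = 250,
                       screen_width = 1680,
                       screen_height = 1050,
                       px_per_cm = 35,
                       aoi_width_cm = 16,
                       aoi_half_height_cm = 8.5,
                       seed = 1L) {
  check_positive(n_subjects, "n_subjects")
  check_positive(trials_per_subject, "trials_per_subject")
  check_positive(sample_rate, "sample_rate")
  check_positive(trial_duration, "trial_duration")
  check_positive(fixation_duration_mean, "fixation_duration_mean")
  check_positive(fixation_duration_min, "fixation_duration_min")
  check_positive(saccade_gap, "saccade_gap")
  check_prob(trackloss_rate, "trackloss_rate")
  if (fixation_duration_sd < 0) config_error("`fixation_duration_sd` must be >= 0.")
  if (face_motion_amplitude < 0) config_error("`face_motion_amplitude` must be >= 0.")
  if (trials_per_subject > 2 * n_stimulus_types) {
    config_error("`trials_per_subject` cannot exceed 2 * n_stimulus_types.")
  }
  if (is.null(bias_profile)) {
    bias_profile <- bias_profile(p_lower = 0.5, trial_duration = trial_duration)
  }
  check_bias_profile(bias_profile, trial_duration)

  structure(
    list(
      n_subjects = as.integer(n_subjects),
      trials_per_subject = as.integer(trials_per_subject),
      n_stimulus_types = as.integer(n_stimulus_types),
      sample_rate = sample_rate,
      trial_duration = trial_duration,
      fixation_duration_mean = fixation_duration_mean,
      fixation_duration_sd = fixation_duration_sd,
      fixation_duration_min = fixation_duration_min,
      saccade_gap = saccade_gap,
      trackloss_rate = trackloss_rate,
      bias_profile = bias_profile,
      face_motion_amplitude = face_motion_amplitude,
      fixation_jitter_sd = fixation_jitter_sd,
      min_saccade_px = min_saccade_px,
      screen_width = screen_width,
      screen_height = screen_height,
      px_per_cm = px_per_cm,
      aoi_width_cm = aoi_width_cm,
      aoi_half_height_cm = aoi_half_height_cm,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Build a lower-AOI bias profile
#'
#' A bias profile maps (condition, trial time) to the probability that a
#' newly planted fixation targets the lower face half. It is stored as a
#' tibble of windows; later rows override earlier ones where they overlap,
#' and times not covered by any row fall back to 0.5 (chance).
#'
#' @param p_lower Probability that a fixation targets the lower AOI inside
#'   the window.
#' @param onset_ms,offset_ms Window bounds in ms (half-open).
#' @param condition Stimulus condition the window applies to, or `"all"`.
#' @param trial_duration Used for the default full-trial window.
#' @return A tibble with columns `condition`, `onset_ms`, `offset_ms`,
#'   `p_lower`.
#' @export
#' @examples
#' bias_profile(p_lower = 0.7)
bias_profile <- function(p_lower = 0.5, onset_ms = 0, offset_ms = trial_duration,
                         condition = "all", trial_duration = 7500) {
  check_prob(p_lower, "p_lower")
  tibble(
    condition = condition,
    onset_ms = onset_ms,
    offset_ms = offset_ms,
    p_lower = p_lower
  )
}

check_bias_profile <- function(profile, trial_duration) {
  check_columns(profile, c("condition", "onset_ms", "offset_ms", "p_lower"),
                "bias_profile")
  check_prob(profile$p_lower, "bias_profile$p_lower")
  if (any(profile$onset_ms < 0) || any(profile$offset_ms > trial_duration) ||
      any(profile$onset_ms >= profile$offset_ms)) {
    config_error("bias_profile windows must satisfy 0 <= onset < offset <= trial_duration.")
  }
  invisible(profile)
}

# Evaluate the profile at one (condition, time): last matching row wins;
# uncovered times are chance (0.5).
bias_at <- function(profile, condition, t) {
  hit <- (profile$condition == "all" | profile$condition == condition) &
    profile$onset_ms <= t & t < profile$offset_ms
  if (!any(hit)) return(0.5)
  profile$p_lower[max(which(hit))]
}

#' Add a bias window to a simulation configuration
#'
#' Returns a new configuration whose lower-AOI bias equals the baseline
#' profile outside `window` and baseline + `magnitude` inside it. Used to
#' plant a known above-chance episode for recovery and power studies.
#'
#' @param config A [sim_config()].
#' @param window Length-2 numeric, `c(onset_ms, offset_ms)` within
#'   `[0, trial_duration]`.
#' @param magnitude Probability shift added inside the window; the shifted
#'   probabilities must stay in `[0, 1]`.
#' @param condition Condition to bias, or `"all"` (default).
#' @return A modified `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 2, seed = 1)
#' biased <- inject_bias(cfg, window = c(2000, 4000), magnitude = 0.25)
inject_bias <- function(config, window, magnitude, condition = "all") {
  stopifnot(inherits(config, "sim_config"))
  if (length(window) != 2 || window[1] < 0 || window[2] > config$trial_duration ||
      window[1] >= window[2]) {
    config_error("`window` must lie within [0, trial_duration] with onset < offset.")
  }
  if (magnitude == 0) return(config)

  profile <- config$bias_profile
  # Baseline may vary inside the window: split at every profile breakpoint
  # so each appended row carries its own shifted level.
  cuts <- sort(unique(c(
    window,
    profile$onset_ms[profile$onset_ms > window[1] & profile$onset_ms < window[2]],
    profile$offset_ms[profile$offset_ms > window[1] & profile$offset_ms < window[2]]
  )))
  pieces <- purrr::map2_dfr(
    cuts[-length(cuts)], cuts[-1],
    function(a, b) {
      base <- bias_at(profile, condition, a)
      tibble(
        condition = condition, onset_ms = a, offset_ms = b,
        p_lower = base + magnitude
      )
    }
  )
  if (any(pieces$p_lower < 0) || any(pieces$p_lower > 1)) {
    config_error("Injected bias pushes a probability outside [0, 1].")
  }
  config$bias_profile <- bind_rows(profile, pieces)
  config
}
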