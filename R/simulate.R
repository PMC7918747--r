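# Synthetic eye-tracking sessions with known ground truth.

#' Stimulus condition table for a simulation configuration
#'
#' With the default four stimulus types this is the 2 x 2 crossing of face
#' race (Asian American, White) and speech type (infant-directed,
#' adult-directed); fewer types take the first rows of that crossing.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `stimulus_id`, `face_race`, `speech_type`.
#' @export
sim_conditions <- function(config) {
  full <- tibble(
    stimulus_id = c("AA_ID", "AA_AD", "W_ID", "W_AD"),
    face_race = c("Asian American", "Asian American", "White", "White"),
    speech_type = c("infant-directed", "adult-directed",
                    "infant-directed", "adult-directed")
  )
  if (config$n_stimulus_types > nrow(full)) {
    config_error("At most 4 stimulus types are supported.")
  }
  full[seq_len(config$n_stimulus_types), ]
}

# Smooth planar position of the stimulus face centre at time t (ms),
# phase-offset per stimulus so the four videos move differently.
face_center <- function(config, stim_index, t) {
  a <- config$face_motion_amplitude
  ph <- 2 * pi * stim_index / 4
  list(
    x = config$screen_width / 2 +
      a * sin(2 * pi * t / config$trial_duration + ph),
    y = config$screen_height / 2 +
      a * sin(3 * pi * t / config$trial_duration + ph + pi / 3)
  )
}

#' Dynamic AOI trajectory for one stimulus
#'
#' Two stacked, abutting rectangles of equal size (the upper and lower
#' halves of the face) that translate smoothly with the simulated face
#' centre. Each half is `aoi_width_cm` wide by `aoi_half_height_cm` high at
#' the configured px/cm scale; at every timestamp the upper rectangle's
#' bottom edge coincides with the lower rectangle's top edge.
#'
#' @param config A [sim_config()].
#' @param stimulus_id One of the ids from [sim_conditions()].
#' @return Tibble with columns `stimulus_id`, `time_ms`, `region`
#'   (`"upper"`/`"lower"`), `x_min`, `y_min`, `x_max`, `y_max`, one pair of
#'   rows per sample timestamp.
#' @export
make_aoi_trajectory <- function(config, stimulus_id) {
  conds <- sim_conditions(config)
  stim_index <- match(stimulus_id, conds$stimulus_id)
  if (is.na(stim_index)) config_error("Unknown `stimulus_id`.")
  times <- sample_times(config)
  fc <- face_center(config, stim_index, times)
  w <- config$aoi_width_cm * config$px_per_cm
  h <- config$aoi_half_height_cm * config$px_per_cm
  bind_rows(
    tibble(
      stimulus_id = stimulus_id, time_ms = times, region = "upper",
      x_min = fc$x - w / 2, y_min = fc$y - h,
      x_max = fc$x + w / 2, y_max = fc$y
    ),
    tibble(
      stimulus_id = stimulus_id, time_ms = times, region = "lower",
      x_min = fc$x - w / 2, y_min = fc$y,
      x_max = fc$x + w / 2, y_max = fc$y + h
    )
  ) %>%
    arrange(.data$time_ms, .data$region)
}

sample_times <- function(config) {
  n <- round(config$trial_duration / 1000 * config$sample_rate)
  (seq_len(n) - 1) * (1000 / config$sample_rate)
}

# Plan the fixation sequence for one trial. RNG must already be seeded.
# All boundaries are aligned to the sample grid (durations and the saccade
# gap are whole numbers of sample periods), so planted onsets/offsets are
# exactly recoverable by the detector. Returns start/end (ms), target AOI,
# and the gaze point relative to the face centre. The last fixation is
# extended to the trial end so every sample is covered by a fixation or a
# saccade gap.
plan_fixations <- function(config, condition) {
  margin <- 40
  w <- config$aoi_width_cm * config$px_per_cm
  h <- config$aoi_half_height_cm * config$px_per_cm
  p <- 1000 / config$sample_rate
  n_total <- round(config$trial_duration / 1000 * config$sample_rate)
  min_idx <- ceiling(config$fixation_duration_min / p)
  gap_idx <- max(1L, round(config$saccade_gap / p))
  starts <- ends <- integer(0) # sample indices
  relx <- rely <- numeric(0)
  target <- character(0)
  t_idx <- 0L
  prev_x <- prev_y <- NA_real_
  while (t_idx + min_idx <= n_total) {
    d_ms <- rnorm(1, config$fixation_duration_mean,
                  config$fixation_duration_sd)
    d_idx <- max(round(d_ms / p), min_idx)
    d_idx <- min(d_idx, n_total - t_idx)
    p_low <- bias_at(config$bias_profile, condition, t_idx * p)
    is_lower <- runif(1) < p_low
    # Resample the target point until the saccade amplitude reaches
    # min_saccade_px, so consecutive fixations cannot blur into one.
    for (attempt in 1:50) {
      rx <- runif(1, -w / 2 + margin, w / 2 - margin)
      ry <- if (is_lower) runif(1, margin, h - margin)
            else runif(1, -h + margin, -margin)
      if (is.na(prev_x) ||
          sqrt((rx - prev_x)^2 + (ry - prev_y)^2) >= config$min_saccade_px) {
        break
      }
    }
    starts <- c(starts, t_idx)
    ends <- c(ends, t_idx + d_idx)
    target <- c(target, if (is_lower) "lower" else "upper")
    relx <- c(relx, rx)
    rely <- c(rely, ry)
    prev_x <- rx
    prev_y <- ry
    t_idx <- t_idx + d_idx + gap_idx
  }
  if (length(ends) > 0) ends[length(ends)] <- n_total
  tibble(start_ms = starts * p, end_ms = ends * p, target_aoi = target,
         rel_x = relx, rel_y = rely)
}

# Emit the raw samples for one trial given its fixation plan. RNG seeded.
trial_samples <- function(config, stim_index, plan) {
  times <- sample_times(config)
  n <- length(times)
  idx <- findInterval(times, plan$start_ms)
  in_fix <- idx >= 1 & times < plan$end_ms[pmax(idx, 1)]
  fc <- face_center(config, stim_index, times)

  x <- y <- numeric(n)
  # Fixation samples track the moving face around the planted gaze point.
  fi <- idx[in_fix]
  x[in_fix] <- fc$x[in_fix] + plan$rel_x[fi] +
    rnorm(sum(in_fix), 0, config$fixation_jitter_sd)
  y[in_fix] <- fc$y[in_fix] + plan$rel_y[fi] +
    rnorm(sum(in_fix), 0, config$fixation_jitter_sd)

  # Saccade samples interpolate linearly between the bounding centroids.
  gap <- !in_fix
  if (any(gap)) {
    k <- idx[gap] # fixation just ended (>=1 because first fixation starts at 0)
    t0 <- plan$end_ms[k]
    t1 <- plan$start_ms[k + 1]
    fc0 <- face_center(config, stim_index, t0)
    fc1 <- face_center(config, stim_index, t1)
    # Saccade samples are drawn from the mid-flight portion of the path
    # (path fraction 0.4-0.6), so with min_saccade_px = 250 every saccade
    # sample lies >= 100 px from both fixation points and can never be
    # captured by a fixation window of the dispersion filter.
    period <- 1000 / config$sample_rate
    u <- (times[gap] - t0 + period) / (t1 - t0 + period)
    frac <- 0.4 + 0.2 * u
    x[gap] <- (1 - frac) * (fc0$x + plan$rel_x[k]) +
      frac * (fc1$x + plan$rel_x[k + 1])
    y[gap] <- (1 - frac) * (fc0$y + plan$rel_y[k]) +
      frac * (fc1$y + plan$rel_y[k + 1])
  }

  lost <- runif(n) < config$trackloss_rate
  x[lost] <- NA_real_
  y[lost] <- NA_real_
  tibble(time_ms = times, x_px = x, y_px = y,
         valid = as.integer(!lost))
}

# Subject covariates: raw parental-report fields plus the generator's own
# true classification labels (computed inline, independently of the
# classify_* functions, so label recovery is a real cross-check). RNG seeded.
subject_profile <- function(subject_id) {
  age_days <- sample(217:320, 1)

  true_race <- sample(c("White", "Asian American", "Other"), 1,
                      prob = c(0.45, 0.25, 0.30))
  hispanic <- FALSE
  races <- switch(true_race,
    "White" = {
      hispanic <- runif(1) < 0.2
      "White"
    },
    "Asian American" = if (runif(1) < 0.5) "Asian American"
                       else "Asian American+White",
    "Other" = {
      pick <- sample(c("Black", "Other", "none"), 1)
      if (pick == "none") {
        hispanic <- TRUE
        ""
      } else pick
    }
  )

  caregiver <- if (runif(1) < 0.6) true_race else
    sample(c("White", "Asian American", "Other", NA_character_), 1)
  quest <- runif(1) < 0.9
  exp_white <- quest & runif(1) < 0.6
  exp_asian <- quest & runif(1) < 0.4
  exp_black <- quest & runif(1) < 0.3

  true_div <- if (!quest) NA_character_ else {
    groups <- unique(c(
      true_race,
      if (!is.na(caregiver)) caregiver,
      if (exp_white) "White",
      if (exp_asian) "Asian American",
      if (exp_black) "Black"
    ))
    c("low", "medium", "high")[pmin(length(groups), 3)]
  }

  lang_cat <- sample(
    c("monolingual English", "multilingual", "other monolingual", "unreported"),
    1, prob = c(0.67, 0.23, 0.06, 0.04)
  )
  lang_english <- lang_other <- NA_real_
  lang_other_name <- NA_character_
  if (lang_cat == "monolingual English") {
    lang_english <- runif(1, 0.8, 1)
    lang_other <- 1 - lang_english
    lang_other_name <- "Spanish"
  } else if (lang_cat == "multilingual") {
    lang_english <- runif(1, 0.3, 0.7)
    lang_other <- 1 - lang_english
    lang_other_name <- sample(c("Spanish", "Mandarin", "Korean"), 1)
  } else if (lang_cat == "other monolingual") {
    lang_other <- runif(1, 0.8, 1)
    lang_english <- 1 - lang_other
    lang_other_name <- sample(c("Mandarin", "Korean"), 1)
  }

  tibble(
    subject_id = subject_id,
    age_days = age_days,
    mother_races = races,
    mother_hispanic = hispanic,
    caregiver_race = caregiver,
    questionnaire_present = quest,
    exp_white = exp_white,
    exp_asian = exp_asian,
    exp_black = exp_black,
    lang_english = lang_english,
    lang_other = lang_other,
    lang_other_name = lang_other_name,
    true_mother_race = true_race,
    true_diversity = true_div,
    true_language = lang_cat
  )
}

#' Simulate a complete synthetic eye-tracking session
#'
#' Generates raw 120 Hz gaze samples for a cohort of infants viewing moving
#' face stimuli, together with the ground truth needed to validate every
#' downstream stage: the planted fixation intervals and their target AOIs,
#' the dynamic AOI trajectories, and subject covariates with known
#' classification labels.
#'
#' Each trial is a sequence of planted fixations separated by short saccade
#' gaps. A fixation targets the lower face half with the probability given
#' by the configuration's bias profile at its onset; its gaze point tracks
#' the moving face with isotropic jitter, so planted fixations stay within
#' the dispersion cap of the detector. Samples during saccades interpolate
#' between the bounding fixation positions; track-lost samples are flagged
#' invalid with missing coordinates.
#'
#' Every (subject, trial) pair draws from its own random stream derived
#' from `config$seed`, so the output is bit-identical for identical
#' configurations and unaffected for subject k by adding or removing other
#' subjects.
#'
#' @param config A [sim_config()].
#' @return A list of class `gaze_session` with elements
#'   \describe{
#'     \item{samples}{raw sample tibble: `subject_id`, `trial_number`,
#'       `stimulus_id`, `face_race`, `speech_type`, `time_ms`, `x_px`,
#'       `y_px`, `valid` (0/1)}
#'     \item{aoi}{dynamic AOI trajectories, one per stimulus
#'       (see [make_aoi_trajectory()])}
#'     \item{subjects}{per-subject covariates incl. `true_*` labels}
#'     \item{planted}{ground-truth fixations: `subject_id`, `trial_number`,
#'       `stimulus_id`, `start_ms`, `end_ms`, `target_aoi`}
#'   }
#' @export
#' @examples
#' sess <- simulate_session(sim_config(n_subjects = 2, seed = 42))
#' dplyr::count(sess$samples, subject_id, trial_number)
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  conds <- sim_conditions(config)

  aoi <- purrr::map_dfr(conds$stimulus_id,
                        ~ make_aoi_trajectory(config, .x))

  per_subject <- purrr::map(seq_len(config$n_subjects), function(i) {
    sid <- sprintf("S%03d", i)
    # Subject-level stream (trial 0): covariates and trial order.
    sub <- withr::with_seed(derive_seed(config$seed, i, 0L), {
      prof <- subject_profile(sid)
      schedule <- sample(rep(seq_len(config$n_stimulus_types), 2))
      list(profile = prof,
           schedule = schedule[seq_len(config$trials_per_subject)])
    })

    trials <- purrr::map(seq_len(config$trials_per_subject), function(tr) {
      stim_index <- sub$schedule[tr]
      cond <- conds[stim_index, ]
      withr::with_seed(derive_seed(config$seed, i, tr), {
        plan <- plan_fixations(config, cond$stimulus_id)
        smp <- trial_samples(config, stim_index, plan)
        smp$subject_id <- sid
        smp$trial_number <- tr
        smp$stimulus_id <- cond$stimulus_id
        smp$face_race <- cond$face_race
        smp$speech_type <- cond$speech_type
        pl <- plan[, c("start_ms", "end_ms", "target_aoi")]
        pl$subject_id <- sid
        pl$trial_number <- tr
        pl$stimulus_id <- cond$stimulus_id
        list(
          samples = smp[, c("subject_id", "trial_number", "stimulus_id",
                            "face_race", "speech_type", "time_ms", "x_px",
                            "y_px", "valid")],
          planted = pl[, c("subject_id", "trial_number", "stimulus_id",
                           "start_ms", "end_ms", "target_aoi")]
        )
      })
    })
    list(
      profile = sub$profile,
      samples = purrr::map_dfr(trials, "samples"),
      planted = purrr::map_dfr(trials, "planted")
    )
  })

  structure(
    list(
      samples = purrr::map_dfr(per_subject, "samples"),
      aoi = aoi,
      subjects = purrr::map_dfr(per_subject, "profile"),
      planted = purrr::map_dfr(per_subject, "planted")
    ),
    class = "gaze_session"
  )
}

#' @export
print.gaze_session <- function(x, ...) {
  cat("<gaze_session>\n")
  cat(sprintf("  %d subjects, %d trials, %d samples\n",
              dplyr::n_distinct(x$samples$subject_id),
              nrow(distinct(x$samples, .data$subject_id, .data$trial_number)),
              nrow(x$samples)))
  invisible(x)
}
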