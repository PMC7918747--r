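test_that("trial sample counts and timing follow the acquisition design", {
  cfg <- sim_config(n_subjects = 1, trials_per_subject = 2, seed = 1)
  sess <- simulate_session(cfg)
  per_trial <- dplyr::count(sess$samples, trial_number)
  expect_true(all(per_trial$n == 900)) # 7500 ms at 120 Hz
  t1 <- dplyr::filter(sess$samples, trial_number == 1)
  expect_equal(diff(t1$time_ms), rep(1000 / 120, 899))
  expect_equal(t1$time_ms[1], 0)
})

test_that("identical seed and config give bit-identical output", {
  cfg <- sim_config(n_subjects = 2, trials_per_subject = 3, seed = 99,
                    trackloss_rate = 0.1)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$planted, s2$planted)
  expect_identical(s1$subjects, s2$subjects)
})

test_that("adding subjects does not perturb existing subjects' data", {
  small <- simulate_session(sim_config(n_subjects = 2, seed = 7))
  big <- simulate_session(sim_config(n_subjects = 4, seed = 7))
  expect_identical(
    small$samples,
    dplyr::filter(big$samples, subject_id %in% c("S001", "S002"))
  )
})

test_that("zero track loss gives all-valid samples; positive rate converges", {
  sess0 <- simulate_session(sim_config(n_subjects = 1, seed = 3,
                                       trackloss_rate = 0))
  expect_true(all(sess0$samples$valid == 1))

  rate <- 0.2
  sess <- simulate_session(sim_config(n_subjects = 3, trials_per_subject = 4,
                                      seed = 3, trackloss_rate = rate))
  n <- nrow(sess$samples) # 10800 >= 1e4
  phat <- mean(sess$samples$valid == 0)
  ci <- rate + c(-1, 1) * stats::qnorm(0.995) * sqrt(rate * (1 - rate) / n)
  expect_gt(phat, ci[1])
  expect_lt(phat, ci[2])
})

test_that("planted fixations are ordered, non-overlapping, long enough", {
  sess <- simulate_session(sim_config(n_subjects = 3, seed = 5))
  by_trial <- split(sess$planted,
                    paste(sess$planted$subject_id, sess$planted$trial_number))
  for (tr in by_trial) {
    expect_true(!is.unsorted(tr$start_ms, strictly = TRUE))
    expect_true(all(tr$start_ms[-1] >= tr$end_ms[-nrow(tr)]))
  }
  expect_true(all(sess$planted$end_ms - sess$planted$start_ms >= 100))
})

test_that("AOI trajectories are equal-sized, abutting, correctly sized", {
  cfg <- sim_config(n_subjects = 1, seed = 2)
  aoi <- make_aoi_trajectory(cfg, "W_ID")
  up <- dplyr::filter(aoi, region == "upper")
  lo <- dplyr::filter(aoi, region == "lower")
  # 8.5 cm x 16 cm at the pinned 35 px/cm scale
  expect_equal(up$x_max - up$x_min, rep(16 * 35, nrow(up)))
  expect_equal(up$y_max - up$y_min, rep(8.5 * 35, nrow(up)))
  expect_equal(lo$y_max - lo$y_min, rep(8.5 * 35, nrow(lo)))
  # upper's bottom edge is lower's top edge at every timestamp
  expect_equal(up$y_max, lo$y_min)
  expect_equal(up$x_min, lo$x_min)
  # zero amplitude freezes the rectangles
  cfg0 <- sim_config(n_subjects = 1, seed = 2, face_motion_amplitude = 0)
  aoi0 <- make_aoi_trajectory(cfg0, "W_ID")
  expect_equal(length(unique(aoi0$x_min)), 1)
  expect_equal(length(unique(aoi0$y_min)), 2) # one per region
})

test_that("configured lower-AOI bias is reproduced in planted fixation time", {
  p <- 0.7
  cfg <- sim_config(n_subjects = 40, trials_per_subject = 8, seed = 21,
                    trackloss_rate = 0,
                    bias_profile = bias_profile(p_lower = p))
  sess <- simulate_session(cfg)
  pl <- sess$planted
  n_fix <- nrow(pl)
  frac_fix <- mean(pl$target_aoi == "lower")
  ci <- p + c(-1, 1) * stats::qnorm(0.995) * sqrt(p * (1 - p) / n_fix)
  expect_gt(frac_fix, ci[1])
  expect_lt(frac_fix, ci[2])
  # fixation *time* fraction agrees too (durations independent of target)
  dur <- pl$end_ms - pl$start_ms
  frac_time <- sum(dur[pl$target_aoi == "lower"]) / sum(dur)
  expect_lt(abs(frac_time - p), 0.03)
})

test_that("inject_bias shifts the profile only inside the window", {
  base <- sim_config(n_subjects = 20, trials_per_subject = 8, seed = 31,
                     trackloss_rate = 0)
  expect_identical(inject_bias(base, c(2000, 4000), 0), base)

  biased <- inject_bias(base, c(2000, 4000), 0.25)
  sess <- simulate_session(biased)
  pl <- sess$planted
  inside <- pl$start_ms >= 2000 & pl$start_ms < 4000
  expect_lt(abs(mean(pl$target_aoi[inside] == "lower") - 0.75), 0.04)
  expect_lt(abs(mean(pl$target_aoi[!inside] == "lower") - 0.50), 0.04)

  # full-window injection behaves as a constant profile
  full <- inject_bias(base, c(0, 7500), 0.2)
  const <- sim_config(n_subjects = 20, trials_per_subject = 8, seed = 31,
                      trackloss_rate = 0,
                      bias_profile = bias_profile(p_lower = 0.7))
  expect_identical(simulate_session(full)$samples,
                   simulate_session(const)$samples)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(trackloss_rate = 1.2), class = "gazecourse_config_error")
  expect_error(sim_config(trial_duration = -5), class = "gazecourse_config_error")
  expect_error(sim_config(bias_profile = bias_profile(p_lower = 0.5,
                                                      onset_ms = -10)),
               class = "gazecourse_config_error")
  cfg <- sim_config(n_subjects = 1)
  expect_error(inject_bias(cfg, c(2000, 4000), 0.7),
               class = "gazecourse_config_error")
  expect_error(inject_bias(cfg, c(-1, 4000), 0.1),
               class = "gazecourse_config_error")
})

test_that("planted fixations round-trip through the detector", {
  cfg <- sim_config(n_subjects = 4, trials_per_subject = 4, seed = 13,
                    trackloss_rate = 0)
  sess <- simulate_session(cfg)
  fx <- detect_fixations(sess$samples, detector_config())
  period <- 1000 / 120
  planted <- dplyr::filter(sess$planted, end_ms - start_ms >= 120)
  hits <- purrr::pmap_lgl(
    planted,
    function(subject_id, trial_number, start_ms, end_ms, ...) {
      cand <- fx[fx$subject_id == subject_id &
                   fx$trial_number == trial_number, ]
      any(abs(cand$start_ms - start_ms) <= 2 * period &
            abs(cand$end_ms - end_ms) <= 2 * period)
    }
  )
  expect_gte(mean(hits), 0.95)
})
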