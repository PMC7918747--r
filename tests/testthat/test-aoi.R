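# Static two-row AOI table: upper [0,200)x[0,100], lower [0,200)x[100,200).
static_aoi <- function(stimulus_id = "AA_ID") {
  tibble::tibble(
    stimulus_id = stimulus_id,
    time_ms = c(0, 0),
    region = c("upper", "lower"),
    x_min = 0, y_min = c(0, 100), x_max = 200, y_max = c(100, 200)
  )
}

aoi_samples <- function(x, y, time_ms = NULL, valid = NULL) {
  n <- length(x)
  if (is.null(time_ms)) time_ms <- (seq_len(n) - 1) * (1000 / 120)
  if (is.null(valid)) valid <- rep(1L, n)
  tibble::tibble(
    subject_id = "S1", trial_number = 1L, stimulus_id = "AA_ID",
    time_ms = time_ms, x_px = x, y_px = y, valid = valid
  )
}

test_that("point-in-rectangle labelling with upper priority on the shared edge", {
  smp <- aoi_samples(x = c(100, 100, 100, 300, 100),
                     y = c(150, 50, 100, 150, 250))
  lab <- label_samples(smp, static_aoi())
  expect_equal(lab$aoi, c("lower", "upper", "upper", "none", "none"))
  # scalar helper agrees
  expect_equal(assign_sample_aoi(100, 150, c(0, 0, 200, 100),
                                 c(0, 100, 200, 200)), "lower")
  expect_equal(assign_sample_aoi(100, 100, c(0, 0, 200, 100),
                                 c(0, 100, 200, 200)), "upper")
})

test_that("the same screen point flips label when the face moves", {
  # face (and both AOIs) shift up by one half-height at t = 100 ms: the
  # screen point that was in the upper half now falls in the lower half
  moving <- dplyr::bind_rows(
    static_aoi(),
    dplyr::mutate(static_aoi(), time_ms = 100,
                  y_min = y_min - 100, y_max = y_max - 100)
  )
  smp <- aoi_samples(x = c(100, 100), y = c(50, 50), time_ms = c(0, 100))
  lab <- label_samples(smp, moving)
  expect_equal(lab$aoi, c("upper", "lower"))
})

test_that("invalid samples get NA and labels partition the valid samples", {
  smp <- aoi_samples(x = c(100, NA, 100), y = c(50, NA, 400),
                     valid = c(1L, 0L, 1L))
  lab <- label_samples(smp, static_aoi())
  expect_equal(lab$aoi, c("upper", NA, "none"))

  sess <- simulate_session(sim_config(n_subjects = 2, seed = 17,
                                      trackloss_rate = 0.1))
  lab2 <- label_samples(sess$samples, sess$aoi)
  counts <- dplyr::summarise(
    dplyr::group_by(lab2, subject_id, trial_number),
    n_valid = sum(valid == 1),
    n_labelled = sum(!is.na(aoi))
  )
  expect_equal(counts$n_labelled, counts$n_valid)
})

test_that("missing AOI coverage raises a data error", {
  aoi_late <- dplyr::mutate(static_aoi(), time_ms = 500)
  expect_error(label_samples(aoi_samples(100, 150), aoi_late),
               class = "gazecourse_data_error")
  expect_error(
    label_samples(dplyr::mutate(aoi_samples(100, 150),
                                stimulus_id = "W_AD"),
                  static_aoi()),
    class = "gazecourse_data_error"
  )
})

test_that("fixation AOI is the majority of member samples with tie-breaks", {
  aoi <- static_aoi()
  mk_fix <- function(n) tibble::tibble(
    subject_id = "S1", trial_number = 1L, fixation_index = 1L,
    start_ms = 0, end_ms = n * 1000 / 120,
    duration_ms = n * 1000 / 120, centroid_x = 0, centroid_y = 0,
    n_samples = n
  )
  lab_of <- function(y) {
    smp <- label_samples(aoi_samples(rep(100, length(y)), y), aoi)
    label_fixations(mk_fix(length(y)), smp)$aoi
  }
  expect_equal(lab_of(rep(150, 10)), "lower")                     # unanimous
  expect_equal(lab_of(c(rep(150, 6), rep(50, 4))), "lower")       # 60/40
  expect_equal(lab_of(c(50, 150, 50, 150)), "upper")              # tie -> first
  expect_equal(lab_of(c(150, 50, 150, 50)), "lower")              # tie -> first
  expect_equal(lab_of(c(400, 400, 400, 150)), "none")             # none majority
})

test_that("a fixation whose samples are mostly outside both AOIs is none", {
  aoi <- static_aoi()
  smp <- label_samples(aoi_samples(rep(300, 10), rep(150, 10)), aoi)
  fix <- tibble::tibble(
    subject_id = "S1", trial_number = 1L, fixation_index = 1L,
    start_ms = 0, end_ms = 10 * 1000 / 120,
    duration_ms = 10 * 1000 / 120, centroid_x = 300, centroid_y = 150,
    n_samples = 10
  )
  expect_equal(label_fixations(fix, smp)$aoi, "none")
})

test_that("trial inclusion is >= 1000 ms of summed fixation time, inclusive", {
  mk <- function(durs, trial) tibble::tibble(
    subject_id = "S1", trial_number = trial,
    duration_ms = durs
  )
  fx <- dplyr::bind_rows(mk(c(500, 499), 1L),   # 999 -> drop
                         mk(c(600, 400), 2L),   # 1000 -> keep
                         mk(5876.70, 3L))       # typical kept trial
  inc <- apply_trial_exclusion(fx)
  expect_equal(inc$keep, c(FALSE, TRUE, TRUE))
  expect_equal(inc$total_looking_ms, c(999, 1000, 5876.70))
  kept <- exclude_trials(fx, inc)
  expect_equal(sort(unique(kept$trial_number)), c(2L, 3L))
})

test_that("excluding one trial never alters another trial's outputs", {
  sess <- simulate_session(sim_config(n_subjects = 1, trials_per_subject = 4,
                                      seed = 23))
  fx <- detect_fixations(sess$samples)
  inc <- apply_trial_exclusion(fx)
  inc_forced <- dplyr::mutate(inc, keep = trial_number != 2L)
  kept <- exclude_trials(fx, inc_forced)
  expect_equal(
    dplyr::filter(kept, trial_number == 3L),
    dplyr::filter(fx, trial_number == 3L)
  )
})
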