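# End-to-end runs: simulate or load raw tables, preprocess, aggregate,
# bin, test, and write the publication-style outputs with a manifest.

#' Pipeline run configuration
#'
#' Inputs are either a [sim_config()] (synthetic session) or paths to the
#' three raw CSVs (samples, AOI trajectories, subject covariates) in the
#' schemas written by [write_session()].
#'
#' @param sim A [sim_config()], or `NULL` when reading CSVs.
#' @param samples_csv,aoi_csv,subjects_csv Input paths (ignored when `sim`
#'   is given).
#' @param detector A [detector_config()].
#' @param bins A [bin_config()].
#' @param perm A [perm_config()].
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = NULL, samples_csv = NULL, aoi_csv = NULL,
                       subjects_csv = NULL, detector = detector_config(),
                       bins = bin_config(), perm = perm_config(),
                       out_dir = NULL) {
  if (is.null(sim) && (is.null(samples_csv) || is.null(aoi_csv))) {
    config_error("Provide either `sim` or `samples_csv` + `aoi_csv`.")
  }
  structure(
    list(sim = sim, samples_csv = samples_csv, aoi_csv = aoi_csv,
         subjects_csv = subjects_csv, detector = detector, bins = bins,
         perm = perm, out_dir = out_dir),
    class = "run_config"
  )
}

#' Write a session's raw tables to CSV
#'
#' @param session A `gaze_session` from [simulate_session()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    samples = file.path(dir, "samples.csv"),
    aoi = file.path(dir, "aoi_trajectories.csv"),
    subjects = file.path(dir, "subjects.csv")
  )
  readr::write_csv(session$samples, paths["samples"])
  readr::write_csv(session$aoi, paths["aoi"])
  readr::write_csv(session$subjects, paths["subjects"])
  invisible(paths)
}

read_session_csvs <- function(cfg) {
  samples <- readr::read_csv(cfg$samples_csv, show_col_types = FALSE)
  check_columns(samples,
                c("subject_id", "trial_number", "stimulus_id", "face_race",
                  "speech_type", "time_ms", "x_px", "y_px", "valid"),
                basename(cfg$samples_csv))
  aoi <- readr::read_csv(cfg$aoi_csv, show_col_types = FALSE)
  check_columns(aoi, c("stimulus_id", "time_ms", "region", "x_min", "y_min",
                       "x_max", "y_max"), basename(cfg$aoi_csv))
  subjects <- NULL
  if (!is.null(cfg$subjects_csv)) {
    subjects <- readr::read_csv(cfg$subjects_csv, show_col_types = FALSE)
    check_columns(subjects, "subject_id", basename(cfg$subjects_csv))
  }
  list(samples = samples, aoi = aoi, subjects = subjects)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) raw gaze samples, labels them by dynamic AOI,
#' detects fixations, applies the trial-inclusion rule, builds trial- and
#' condition-level dependent variables and the long fixation table, bins
#' the labeled samples into 250 ms time courses, and runs the cluster-mass
#' permutation test against chance — collapsed across trial types and
#' separately per stimulus condition. When `cfg$out_dir` is set, all
#' result tables are written as CSV together with a JSON manifest
#' (configs, seed, row counts at every stage) sufficient to reproduce the
#' run.
#'
#' @param cfg A [run_config()].
#' @return List of class `gaze_pipeline`: `fixations`, `inclusion`,
#'   `trial_dvs`, `condition_prefs`, `fixation_table`, `trial_tc`,
#'   `subject_tc`, `subject_tc_cond`, `group_tc`, `group_tc_cond`,
#'   `test_all` (a `gaze_cluster_test`), `tests_by_condition` (named list),
#'   `cluster_report`, `subjects`, `log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$sim)) {
    session <- simulate_session(cfg$sim)
    samples <- session$samples
    aoi <- session$aoi
    subjects <- classify_subjects(session$subjects)
  } else {
    inp <- read_session_csvs(cfg)
    samples <- inp$samples
    aoi <- inp$aoi
    subjects <- inp$subjects
  }

  labeled <- label_samples(samples, aoi)
  fixations <- detect_fixations(samples, cfg$detector) %>%
    label_fixations(labeled)
  inclusion <- apply_trial_exclusion(fixations, cfg$detector)
  if (!any(inclusion$keep)) {
    data_error("No trial passed the minimum-looking inclusion rule; nothing to analyse.")
  }
  fix_kept <- exclude_trials(fixations, inclusion)
  samp_kept <- exclude_trials(labeled, inclusion)

  trial_dvs <- trial_totals(fix_kept)
  cond_prefs <- condition_preference(trial_dvs)
  fix_table <- fixation_table(fix_kept, subjects)

  trial_tc <- bin_trials(samp_kept, cfg$bins)
  subject_tc <- subject_timecourse(trial_tc)
  subject_tc_cond <- subject_timecourse(trial_tc, by_condition = TRUE)
  group_tc <- group_timecourse(subject_tc)
  group_tc_cond <- group_timecourse(subject_tc_cond)

  test_all <- cluster_permutation_test(subject_tc, cfg$perm)
  conds <- arrange(distinct(subject_tc_cond, .data$face_race, .data$speech_type),
                   .data$face_race, .data$speech_type)
  tests_by_condition <- purrr::pmap(conds, function(face_race, speech_type) {
    tc <- filter(subject_tc_cond,
                 .data$face_race == !!face_race,
                 .data$speech_type == !!speech_type)
    cluster_permutation_test(tc, cfg$perm)
  })
  names(tests_by_condition) <- paste(conds$face_race, conds$speech_type,
                                     sep = " / ")

  cluster_report <- bind_rows(
    mutate(tidy(test_all), face_race = "ALL", speech_type = "ALL",
           .before = 1),
    purrr::pmap_dfr(
      list(conds$face_race, conds$speech_type, tests_by_condition),
      function(fr, st, tst) {
        mutate(tidy(tst), face_race = fr, speech_type = st, .before = 1)
      }
    )
  )

  log <- tibble(
    stage = c("samples", "fixations", "trials_total", "trials_kept",
              "trials_dropped", "subjects"),
    n = c(nrow(samples), nrow(fixations), nrow(inclusion),
          sum(inclusion$keep), sum(!inclusion$keep),
          dplyr::n_distinct(samples$subject_id))
  )

  result <- structure(
    list(
      fixations = fix_kept, inclusion = inclusion, trial_dvs = trial_dvs,
      condition_prefs = cond_prefs, fixation_table = fix_table,
      trial_tc = trial_tc, subject_tc = subject_tc,
      subject_tc_cond = subject_tc_cond, group_tc = group_tc,
      group_tc_cond = group_tc_cond, test_all = test_all,
      tests_by_condition = tests_by_condition,
      cluster_report = cluster_report, subjects = subjects, log = log
    ),
    class = "gaze_pipeline"
  )

  if (!is.null(cfg$out_dir)) write_pipeline(result, cfg)
  result
}

# Publication-style CSV bundle + JSON manifest.
write_pipeline <- function(result, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(cfg$out_dir, name)

  readr::write_csv(result$fixations, out("fixations.csv"))
  readr::write_csv(result$trial_dvs, out("trial_dvs.csv"))
  readr::write_csv(result$condition_prefs, out("condition_preferences.csv"))
  readr::write_csv(result$fixation_table, out("fixation_table.csv"))

  tidy_tc <- bind_rows(
    mutate(result$group_tc, scope = "group", subject_id = "ALL",
           face_race = "ALL", speech_type = "ALL", .before = 1),
    mutate(result$group_tc_cond, scope = "group", subject_id = "ALL",
           .before = 1),
    mutate(result$subject_tc, scope = "subject", face_race = "ALL",
           speech_type = "ALL", .before = 1),
    mutate(result$subject_tc_cond, scope = "subject", .before = 1)
  )
  readr::write_csv(tidy_tc, out("timecourses.csv"))

  # Cluster report in the table convention: sum_t to 4 decimals, p to 3
  # (a mass above every null mass prints as 0.000).
  report <- result$cluster_report %>%
    mutate(sum_t = sprintf("%.4f", .data$sum_t),
           p_value = sprintf("%.3f", .data$p_value))
  readr::write_csv(report, out("clusters.csv"))
  readr::write_csv(
    tibble(permutation = seq_along(result$test_all$null$max_abs_masses),
           max_abs_mass = result$test_all$null$max_abs_masses),
    out("null_distribution.csv")
  )

  manifest <- list(
    package = "gazecourse",
    version = as.character(utils::packageVersion("gazecourse")),
    detector = unclass(cfg$detector),
    bins = unclass(cfg$bins),
    perm = unclass(cfg$perm),
    sim = if (!is.null(cfg$sim)) {
      c(unclass(cfg$sim)[setdiff(names(cfg$sim), "bias_profile")],
        list(bias_profile = as.data.frame(cfg$sim$bias_profile)))
    },
    inputs = list(samples_csv = cfg$samples_csv, aoi_csv = cfg$aoi_csv,
                  subjects_csv = cfg$subjects_csv),
    log = as.data.frame(result$log)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(cfg$out_dir)
}

#' @export
print.gaze_pipeline <- function(x, ...) {
  cat("<gaze_pipeline>\n")
  print(as.data.frame(x$log), row.names = FALSE)
  cat("\nCollapsed cluster test:\n")
  print(x$test_all)
  invisible(x)
}
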