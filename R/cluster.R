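# One-sample cluster-mass permutation test of binned proportions against
# chance. Per-bin uncorrected t tests feed maximal runs of consecutively
# significant, same-signed bins; the summed t over a run is its cluster
# mass, and family-wise error is controlled by the permutation
# distribution of the largest absolute cluster mass.

#' Permutation-test configuration
#'
#' @param n_permutations Number of random permutations (default 1000).
#' @param alpha_bin Two-sided significance level of the per-bin t tests
#'   (default 0.05).
#' @param alpha_cluster Family-wise level: a cluster is significant when its
#'   absolute mass exceeds the empirical `1 - alpha_cluster` quantile of the
#'   null (default 0.05, i.e. the 95th percentile).
#' @param chance Chance proportion tested against (default 0.5).
#' @param min_subjects_per_bin Bins with fewer contributing subjects are
#'   untestable (default 2).
#' @param seed Seed for the permutation draws.
#' @param plus_one Use the (1 + #exceedances)/(1 + n) p-value instead of the
#'   pure proportion; default `FALSE`, so a mass above every null entry is
#'   reported as p = 0.000.
#' @return List of class `perm_config`.
#' @export
perm_config <- function(n_permutations = 1000, alpha_bin = 0.05,
                        alpha_cluster = 0.05, chance = 0.5,
                        min_subjects_per_bin = 2, seed = 1L,
                        plus_one = FALSE) {
  check_positive(n_permutations, "n_permutations")
  check_prob(alpha_bin, "alpha_bin")
  check_prob(alpha_cluster, "alpha_cluster")
  if (alpha_bin <= 0 || alpha_bin >= 1 || alpha_cluster <= 0 ||
      alpha_cluster >= 1) {
    config_error("alpha levels must lie strictly between 0 and 1.")
  }
  check_prob(chance, "chance")
  structure(
    list(
      n_permutations = as.integer(n_permutations),
      alpha_bin = alpha_bin,
      alpha_cluster = alpha_cluster,
      chance = chance,
      min_subjects_per_bin = as.integer(min_subjects_per_bin),
      seed = as.integer(seed),
      plus_one = isTRUE(plus_one)
    ),
    class = "perm_config"
  )
}

# Subject x bin matrix from a single-scope subject time course.
timecourse_matrix <- function(subject_tc) {
  cond_cols <- intersect(c("face_race", "speech_type"), names(subject_tc))
  if (length(cond_cols) > 0 &&
      nrow(distinct(subject_tc, dplyr::across(dplyr::all_of(cond_cols)))) > 1) {
    data_error(paste(
      "`subject_tc` spans several conditions; filter to one scope",
      "(or map over conditions) before testing."
    ))
  }
  wide <- subject_tc %>%
    select("subject_id", "bin_index", "proportion_lower") %>%
    tidyr::pivot_wider(names_from = "bin_index",
                       values_from = "proportion_lower") %>%
    arrange(.data$subject_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$subject_id
  m[, order(as.integer(colnames(m))), drop = FALSE]
}

bin_meta <- function(subject_tc) {
  subject_tc %>%
    distinct(.data$bin_index, .data$bin_onset_ms, .data$bin_offset_ms) %>%
    arrange(.data$bin_index)
}

# Vectorised one-sample t tests of matrix columns against `chance`.
# Returns n, mean, t, df, p per column; untestable columns (n < min_n or
# zero variance) get NA t/p.
col_ttests <- function(m, chance, min_n) {
  d <- m - chance
  n <- colSums(!is.na(d))
  dz <- ifelse(is.na(d), 0, d)
  mu <- colSums(dz) / pmax(n, 1)
  ss <- colSums(dz^2)
  v <- (ss - n * mu^2) / pmax(n - 1, 1)
  v <- pmax(v, 0) # guard tiny negative rounding
  testable <- n >= min_n & v > 0
  tval <- ifelse(testable, mu / sqrt(v / n), NA_real_)
  p <- ifelse(testable, 2 * stats::pt(-abs(tval), n - 1), NA_real_)
  list(n = unname(n), mean = unname(mu + chance), t = unname(tval),
       df = unname(n - 1), p = unname(p), testable = unname(testable))
}

#' Per-bin one-sample t tests against chance
#'
#' For each time bin, a one-sample t test of the subjects' bin proportions
#' against the chance value, using only subjects with a non-missing value
#' in that bin. Bins with fewer than `min_subjects_per_bin` subjects or
#' zero variance are untestable (`significant` is `NA`) and never join
#' clusters.
#'
#' @param subject_tc Single-scope output of [subject_timecourse()].
#' @param cfg A [perm_config()].
#' @return Tibble: `bin_index`, `bin_onset_ms`, `bin_offset_ms`, `n`,
#'   `mean`, `t`, `df`, `p`, `significant`.
#' @export
#' @examples
#' # subjects at 0.6, 0.7, 0.8 in one bin give t = 3.464 against 0.5
bin_ttests <- function(subject_tc, cfg = perm_config()) {
  check_columns(subject_tc, c("subject_id", "bin_index", "proportion_lower"),
                "subject_tc")
  m <- timecourse_matrix(subject_tc)
  res <- col_ttests(m, cfg$chance, cfg$min_subjects_per_bin)
  bin_meta(subject_tc) %>%
    mutate(
      n = res$n, mean = res$mean, t = res$t, df = res$df, p = res$p,
      significant = dplyr::if_else(res$testable, res$p < cfg$alpha_bin,
                                   NA)
    )
}

# Maximal runs of consecutive significant bins sharing the sign of t.
# Works on plain vectors; used identically for observed data and
# permutations.
cluster_runs <- function(tval, significant) {
  sig <- !is.na(significant) & significant
  state <- ifelse(sig, sign(tval), 0)
  state[is.na(state)] <- 0
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  list(start = starts[keep], end = ends[keep],
       mass = purrr::map2_dbl(starts[keep], ends[keep],
                              ~ sum(tval[.x:.y])))
}

#' Identify clusters of consecutively significant bins
#'
#' Clusters are maximal runs of consecutive, individually significant bins
#' whose t statistics share a sign; the cluster mass is the (signed) sum of
#' the member t statistics. Single-bin clusters are allowed. Onset is the
#' start of the first member bin and offset the end of the last, on the bin
#' grid.
#'
#' @param tests Output of [bin_ttests()].
#' @return Tibble: `cluster_index`, `mass`, `n_bins`, `start_bin`,
#'   `end_bin`, `onset_ms`, `offset_ms`.
#' @export
find_clusters <- function(tests) {
  check_columns(tests, c("bin_index", "bin_onset_ms", "bin_offset_ms", "t",
                         "significant"), "tests")
  tests <- arrange(tests, .data$bin_index)
  runs <- cluster_runs(tests$t, tests$significant)
  tibble(
    cluster_index = seq_along(runs$start),
    mass = runs$mass,
    n_bins = runs$end - runs$start + 1L,
    start_bin = tests$bin_index[runs$start],
    end_bin = tests$bin_index[runs$end],
    onset_ms = tests$bin_onset_ms[runs$start],
    offset_ms = tests$bin_offset_ms[runs$end]
  )
}

# Sign-flip engine shared by permutation_null() and the tests' enumeration
# oracle: given a signs matrix (one row per permutation, one column per
# subject), return the largest absolute cluster mass per row (0 when a
# permutation yields no cluster).
max_masses_for_signs <- function(m, signs, cfg) {
  d <- m - cfg$chance
  dz <- ifelse(is.na(d), 0, d)
  n <- colSums(!is.na(d))
  ss <- colSums(dz^2) # invariant under sign flips
  denom_n <- pmax(n, 1)
  mu_all <- (signs %*% dz) / rep(denom_n, each = nrow(signs))
  v_all <- (rep(ss, each = nrow(signs)) - rep(n, each = nrow(signs)) *
              mu_all^2) / rep(pmax(n - 1, 1), each = nrow(signs))
  v_all[v_all < 0] <- 0
  testable <- n >= cfg$min_subjects_per_bin
  apply_row <- function(i) {
    mu <- mu_all[i, ]
    v <- v_all[i, ]
    ok <- testable & v > 0
    tval <- ifelse(ok, mu / sqrt(v / n), NA_real_)
    p <- 2 * stats::pt(-abs(tval), n - 1)
    sig <- ok & !is.na(p) & p < cfg$alpha_bin
    runs <- cluster_runs(tval, sig)
    if (length(runs$mass) == 0) 0 else max(abs(runs$mass))
  }
  vapply(seq_len(nrow(signs)), apply_row, numeric(1))
}

#' Permutation null distribution of the maximum cluster mass
#'
#' Each permutation applies one random sign flip per subject to that
#' subject's entire deviation-from-chance time course
#' (`chance + s_i * (x_ib - chance)`, `s_i` in \{-1, +1\}), preserving the
#' subject's missingness pattern and within-subject autocorrelation. Bin t
#' tests and clusters are recomputed and the largest absolute cluster mass
#' stored (0 when no cluster forms), yielding `n_permutations` null masses.
#' Deterministic given `cfg$seed`.
#'
#' @param subject_tc Single-scope output of [subject_timecourse()].
#' @param cfg A [perm_config()].
#' @return List of class `perm_null`: `max_abs_masses` (length
#'   `n_permutations`), `threshold` (empirical `1 - alpha_cluster`
#'   order-statistic quantile), `n_permutations`.
#' @export
permutation_null <- function(subject_tc, cfg = perm_config()) {
  m <- timecourse_matrix(subject_tc)
  if (nrow(m) < 2) data_error("Permutation test needs at least 2 subjects.")
  signs <- withr::with_seed(
    cfg$seed,
    matrix(sample(c(-1, 1), cfg$n_permutations * nrow(m), replace = TRUE),
           nrow = cfg$n_permutations)
  )
  masses <- max_masses_for_signs(m, signs, cfg)
  structure(
    list(
      max_abs_masses = masses,
      threshold = null_threshold(masses, cfg$alpha_cluster),
      n_permutations = cfg$n_permutations
    ),
    class = "perm_null"
  )
}

# Null threshold: the k-th smallest stored mass with
# k = ceiling((1 - alpha) * (B + 1)), the standard finite-sample choice
# that accounts for the observed statistic being exchangeable with the B
# permutation draws, so the familywise size is at most alpha. At B = 1000
# and alpha = 0.05 this is the 951st of 1000 sorted masses -- in practice
# the value that 95% of the null masses lie below.
null_threshold <- function(masses, alpha_cluster) {
  b <- length(masses)
  k <- min(b, ceiling((1 - alpha_cluster) * (b + 1)))
  sort(masses)[k]
}

#' Evaluate observed clusters against the permutation null
#'
#' The p-value of a cluster is the proportion of null maximum masses at
#' least as large as the cluster's absolute mass (so a mass above every
#' null entry prints as 0.000); a cluster is significant when its absolute
#' mass exceeds the null's `1 - alpha_cluster` quantile, i.e. is larger
#' than 95% of the null masses at the default.
#'
#' @param clusters Output of [find_clusters()].
#' @param null Output of [permutation_null()].
#' @param cfg A [perm_config()].
#' @return `clusters` with added `p_value` and `significant` columns.
#' @export
evaluate_clusters <- function(clusters, null, cfg = perm_config()) {
  check_columns(clusters, "mass", "clusters")
  masses <- null$max_abs_masses
  p <- vapply(abs(clusters$mass),
              function(obs) mean(masses >= obs), numeric(1))
  if (cfg$plus_one) {
    p <- (1 + vapply(abs(clusters$mass),
                     function(obs) sum(masses >= obs), numeric(1))) /
      (1 + length(masses))
  }
  mutate(clusters,
         p_value = p,
         significant = abs(.data$mass) > null$threshold)
}

#' Cluster-mass permutation test of a time course against chance
#'
#' Runs the full test on one scope of subject time courses: per-bin
#' uncorrected t tests against chance, clustering of consecutive
#' significant same-signed bins, and evaluation of the observed cluster
#' masses against the sign-flip permutation distribution of the largest
#' absolute cluster mass.
#'
#' @param subject_tc Single-scope output of [subject_timecourse()].
#' @param cfg A [perm_config()].
#' @return Object of class `gaze_cluster_test` with elements `bin_tests`,
#'   `clusters`, `null`, `threshold`, `config`, `n_subjects`. Supports
#'   [tidy()], [glance()], `print()`, and [autoplot()].
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 6, trials_per_subject = 4, seed = 3,
#'                   bias_profile = bias_profile(p_lower = 0.75))
#' sess <- simulate_session(cfg)
#' tc <- sess$samples |>
#'   label_samples(sess$aoi) |>
#'   bin_trials() |>
#'   subject_timecourse()
#' res <- cluster_permutation_test(tc, perm_config(n_permutations = 99))
#' tidy(res)
cluster_permutation_test <- function(subject_tc, cfg = perm_config()) {
  tests <- bin_ttests(subject_tc, cfg)
  clusters <- find_clusters(tests)
  null <- permutation_null(subject_tc, cfg)
  clusters <- evaluate_clusters(clusters, null, cfg)
  structure(
    list(
      bin_tests = tests,
      clusters = clusters,
      null = null,
      threshold = null$threshold,
      config = cfg,
      n_subjects = dplyr::n_distinct(subject_tc$subject_id)
    ),
    class = "gaze_cluster_test"
  )
}

#' @export
print.gaze_cluster_test <- function(x, ...) {
  cat("<gaze_cluster_test>\n")
  cat(sprintf("  %d subjects, %d bins, %d permutations\n",
              x$n_subjects, nrow(x$bin_tests),
              x$null$n_permutations))
  cat(sprintf("  null threshold (%.0fth pct of max |mass|): %.4f\n",
              100 * (1 - x$config$alpha_cluster), x$threshold))
  if (nrow(x$clusters) == 0) {
    cat("  no clusters\n")
  } else {
    print(as.data.frame(tidy(x)), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy the clusters of a permutation test
#'
#' One row per observed cluster, in the reporting convention of the
#' cluster tables: the summed t (`sum_t`), onset/offset in ms on the bin
#' grid, the permutation p-value, and the significance flag.
#'
#' @param x A `gaze_cluster_test`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gaze_cluster_test
#' @export
tidy.gaze_cluster_test <- function(x, ...) {
  x$clusters %>%
    select(cluster_index = "cluster_index", sum_t = "mass",
           onset_ms = "onset_ms", offset_ms = "offset_ms",
           p_value = "p_value", significant = "significant")
}

#' One-row summary of a permutation test
#'
#' @param x A `gaze_cluster_test`.
#' @param ... Unused.
#' @return A tibble with `n_subjects`, `n_bins`, `n_permutations`,
#'   `threshold`, `n_clusters`, `n_significant`, `largest_mass`.
#' @method glance gaze_cluster_test
#' @export
glance.gaze_cluster_test <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects,
    n_bins = nrow(x$bin_tests),
    n_permutations = x$null$n_permutations,
    threshold = x$threshold,
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    largest_mass = if (nrow(x$clusters) == 0) NA_real_
                   else max(abs(x$clusters$mass))
  )
}
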