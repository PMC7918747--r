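# Independent reference implementations used to cross-check the package:
# naive recomputation throughout, no code shared with R/.

oracle_dispersion <- function(x, y) {
  diff(range(x)) + diff(range(y))
}

# Naive I-DT: maximal passing windows found by full dispersion recomputation
# at every step, on one run of valid samples.
oracle_idt_run <- function(time_ms, x, y, min_duration, max_dispersion) {
  n <- length(time_ms)
  period <- if (n > 1) stats::median(diff(time_ms)) else 1000 / 120
  min_samp <- max(1, ceiling(min_duration / period))
  disp <- function(i, j) {
    diff(range(x[i:j])) + diff(range(y[i:j]))
  }
  out <- data.frame(start = integer(0), end = integer(0))
  i <- 1
  while (i + min_samp - 1 <= n) {
    j <- i + min_samp - 1
    if (disp(i, j) <= max_dispersion) {
      while (j < n && disp(i, j + 1) <= max_dispersion) j <- j + 1
      out <- rbind(out, data.frame(start = i, end = j))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# Oracle over a whole trial: split on invalid samples, apply the naive I-DT
# to each valid run, report start/end times and durations.
oracle_fixations <- function(samples, min_duration = 80, max_dispersion = 100) {
  stopifnot(!is.unsorted(samples$time_ms, strictly = TRUE))
  n <- nrow(samples)
  period <- if (n > 1) stats::median(diff(samples$time_ms)) else 1000 / 120
  ok <- samples$valid == 1 & !is.na(samples$x_px) & !is.na(samples$y_px)
  run_id <- cumsum(c(TRUE, diff(ok) != 0))
  out <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                    centroid_x = numeric(0), centroid_y = numeric(0))
  for (r in split(seq_len(n), run_id)) {
    if (!ok[r[1]]) next
    res <- oracle_idt_run(samples$time_ms[r], samples$x_px[r],
                          samples$y_px[r], min_duration, max_dispersion)
    if (nrow(res) == 0) next
    s <- r[res$start]
    e <- r[res$end]
    out <- rbind(out, data.frame(
      start_ms = samples$time_ms[s],
      end_ms = samples$time_ms[e] + period,
      centroid_x = mapply(function(a, b) mean(samples$x_px[a:b]), s, e),
      centroid_y = mapply(function(a, b) mean(samples$y_px[a:b]), s, e)
    ))
  }
  out[order(out$start_ms), , drop = FALSE]
}

# Random single-trial gaze sequences mixing stable segments, jumps, pure
# noise, and optional track loss; independent of the package generator.
random_gaze_trial <- function(n, seed, trackloss = 0) {
  set.seed(seed)
  x <- numeric(n)
  y <- numeric(n)
  i <- 1
  while (i <= n) {
    len <- min(sample(2:45, 1), n - i + 1)
    if (runif(1) < 0.7) {
      cx <- runif(1, 0, 1680)
      cy <- runif(1, 0, 1050)
      spread <- runif(1, 1, 60)
      x[i:(i + len - 1)] <- cx + runif(len, -spread, spread)
      y[i:(i + len - 1)] <- cy + runif(len, -spread, spread)
    } else {
      x[i:(i + len - 1)] <- runif(len, 0, 1680)
      y[i:(i + len - 1)] <- runif(len, 0, 1050)
    }
    i <- i + len
  }
  valid <- as.integer(runif(n) >= trackloss)
  x[valid == 0] <- NA
  y[valid == 0] <- NA
  tibble::tibble(
    subject_id = "S1", trial_number = 1L,
    time_ms = (seq_len(n) - 1) * (1000 / 120),
    x_px = x, y_px = y, valid = valid
  )
}

# Subject x bin matrix -> subject time-course tibble in the package schema.
tc_from_matrix <- function(m, bin_width = 250) {
  n_sub <- nrow(m)
  n_bin <- ncol(m)
  ids <- if (is.null(rownames(m))) sprintf("S%02d", seq_len(n_sub))
         else rownames(m)
  tibble::tibble(
    subject_id = rep(ids, each = n_bin),
    bin_index = rep(0:(n_bin - 1), n_sub),
    bin_onset_ms = bin_index * bin_width,
    bin_offset_ms = (bin_index + 1) * bin_width,
    n_trials = 1L,
    proportion_lower = as.vector(t(m))
  )
}

# Exhaustive sign-flip null: every one of the 2^n per-subject sign
# assignments, per-bin t tests via stats::t.test, clusters via a manual
# scan. Returns the max |cluster mass| for each assignment.
oracle_null_enum <- function(m, chance = 0.5, alpha_bin = 0.05, min_n = 2) {
  n_sub <- nrow(m)
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_sub)))
  apply(grid, 1, function(s) {
    fm <- chance + sweep(m - chance, 1, s, `*`)
    oracle_max_mass(fm, chance, alpha_bin, min_n)
  })
}

oracle_max_mass <- function(fm, chance, alpha_bin, min_n) {
  nb <- ncol(fm)
  tv <- rep(NA_real_, nb)
  sig <- rep(FALSE, nb)
  for (b in seq_len(nb)) {
    v <- fm[, b]
    v <- v[!is.na(v)]
    if (length(v) >= min_n && stats::sd(v) > 0) {
      tt <- stats::t.test(v, mu = chance)
      tv[b] <- unname(tt$statistic)
      sig[b] <- tt$p.value < alpha_bin
    }
  }
  best <- 0
  cur <- 0
  cur_sign <- 0
  for (b in seq_len(nb)) {
    s_b <- if (sig[b]) sign(tv[b]) else 0
    if (s_b != 0 && s_b == cur_sign) {
      cur <- cur + tv[b]
    } else {
      best <- max(best, abs(cur))
      cur <- if (s_b != 0) tv[b] else 0
      cur_sign <- s_b
    }
  }
  max(best, abs(cur))
}

# Small labeled-sample table for binning tests: one trial whose aoi labels
# are given per sample at 120 Hz.
labeled_trial <- function(aoi_labels, subject_id = "S1", trial_number = 1L) {
  n <- length(aoi_labels)
  tibble::tibble(
    subject_id = subject_id, trial_number = trial_number,
    stimulus_id = "AA_ID", face_race = "Asian American",
    speech_type = "infant-directed",
    time_ms = (seq_len(n) - 1) * (1000 / 120),
    x_px = 0, y_px = 0,
    valid = as.integer(!is.na(aoi_labels)),
    aoi = aoi_labels
  )
}
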