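# Internal helpers shared across modules.

# Abort with a consistent class so callers can test for configuration errors.
config_error <- function(msg) {
  rlang::abort(msg, class = "gazecourse_config_error")
}

data_error <- function(msg) {
  rlang::abort(msg, class = "gazecourse_data_error")
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    config_error(sprintf("`%s` must be a probability in [0, 1].", what))
  }
  invisible(x)
}

check_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    config_error(sprintf("`%s` must be strictly positive.", what))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    data_error(sprintf(
      "`%s` is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Deterministic per-(subject, trial) seed derived from the master seed, so
# adding or removing subjects never perturbs another subject's stream.
derive_seed <- function(master, subject_index, trial_number) {
  (as.integer(master) %% 1000003L) * 1009L +
    as.integer(subject_index) * 131071L +
    as.integer(trial_number) * 8191L
}
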