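# Time-course figures: mean line with CI ribbon, chance reference, and
# significance segments beneath, one panel per condition.

#' Plot a group time course with significant clusters
#'
#' Draws the subject-weighted mean proportion of looking toward the lower
#' face half per time bin, with its confidence ribbon, a horizontal
#' reference at chance, and line segments below the traces marking
#' clusters that differed significantly from chance. If the time course
#' carries `face_race`/`speech_type` columns the panels form the face race
#' x speech type grid.
#'
#' @param group_tc Output of [group_timecourse()].
#' @param clusters Optional cluster table with `onset_ms`, `offset_ms`,
#'   `significant`, and (for panelled plots) `face_race`/`speech_type` —
#'   e.g. the `cluster_report` element of [run_pipeline()] or
#'   `tidy(cluster_permutation_test(...))`.
#' @param chance Chance level drawn as a reference line (default 0.5).
#' @return A ggplot object.
#' @export
plot_timecourse <- function(group_tc, clusters = NULL, chance = 0.5) {
  check_columns(group_tc, c("bin_onset_ms", "proportion_lower"), "group_tc")
  by_cond <- all(c("face_race", "speech_type") %in% names(group_tc))
  x_mid <- (group_tc$bin_onset_ms + group_tc$bin_offset_ms) / 2
  df <- mutate(group_tc, t_mid = x_mid)

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_mid,
                                        y = .data$proportion_lower)) +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      fill = "steelblue", alpha = 0.25, na.rm = TRUE
    ) +
    ggplot2::geom_line(colour = "steelblue", na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time in trial (ms)",
                  y = "Proportion looking to lower half") +
    ggplot2::theme_minimal()

  if (!is.null(clusters)) {
    seg <- filter(clusters, .data$significant)
    if (by_cond && all(c("face_race", "speech_type") %in% names(seg))) {
      seg <- filter(seg, .data$face_race != "ALL")
    }
    if (nrow(seg) > 0) {
      p <- p + ggplot2::geom_segment(
        data = seg,
        ggplot2::aes(x = .data$onset_ms, xend = .data$offset_ms),
        y = 0.05, yend = 0.05, linewidth = 1.5, colour = "black",
        inherit.aes = FALSE
      )
    }
  }
  if (by_cond) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$face_race),
      cols = ggplot2::vars(.data$speech_type)
    )
  }
  p
}

#' Autoplot a cluster permutation test
#'
#' Shows the per-bin subject mean with the test's clusters marked; a quick
#' diagnostic view of a single-scope [cluster_permutation_test()].
#'
#' @param object A `gaze_cluster_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gaze_cluster_test
#' @export
autoplot.gaze_cluster_test <- function(object, ...) {
  bt <- object$bin_tests
  df <- tibble(
    t_mid = (bt$bin_onset_ms + bt$bin_offset_ms) / 2,
    mean = bt$mean
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_mid, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = object$config$chance,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(colour = "steelblue", na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time in trial (ms)",
                  y = "Mean proportion to lower half") +
    ggplot2::theme_minimal()
  seg <- filter(object$clusters, .data$significant)
  if (nrow(seg) > 0) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$onset_ms, xend = .data$offset_ms),
      y = 0.05, yend = 0.05, linewidth = 1.5, colour = "black",
      inherit.aes = FALSE
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
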