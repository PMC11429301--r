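#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Plot the segmentation timeline of a report
#'
#' Horizontal bars, one lane per test, colored by status: the at-a-glance
#' view of how the session was carved up.
#'
#' @param object An `mgce_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mgce_report
#' @export
autoplot.mgce_report <- function(object, ...) {
  seg <- filter(object$segments, !is.na(.data$start_s))
  seg$test <- factor(seg$test, levels = rev(MGCE_TESTS))
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_s, xend = .data$end_s,
                   y = .data$test, yend = .data$test,
                   colour = .data$status),
      linewidth = 4
    ) +
    ggplot2::labs(x = "session time (s)", y = NULL,
                  title = paste("Segmentation:", object$session_id)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot gaze-class density curves
#'
#' The three ocular density curves (up, left, right) over a gaze stream,
#' optionally restricted to the ocular phase; the longest dense segment of
#' each class is what the segmenter reports.
#'
#' @param stream A [gaze_stream()].
#' @param phase_bounds Optional `c(start_s, end_s)` restriction.
#' @param window_s Density window (seconds).
#' @return A ggplot object.
#' @export
plot_gaze_density <- function(stream, phase_bounds = NULL, window_s = 5) {
  if (!is.null(phase_bounds)) {
    stream <- stream[stream$t_s >= phase_bounds[1] &
                       stream$t_s < phase_bounds[2], ]
  }
  curves <- purrr::map_dfr(c("up", "left", "right"), function(lab) {
    cv <- gaze_density(stream, lab, window_s = window_s)
    cv$class <- lab
    as_tibble(cv)
  })
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$t_s, .data$density,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "session time (s)", y = "gaze-class density") +
    ggplot2::theme_minimal()
}

#' Plot the head-height trace with detected sit-to-stand events
#'
#' @param pose A [pose_stream()].
#' @param events Optional events tibble from [detect_sit_to_stand()].
#' @param window Optional `c(start_s, end_s)` restriction.
#' @return A ggplot object.
#' @export
plot_head_height <- function(pose, events = NULL, window = NULL) {
  if (!is.null(window)) {
    pose <- pose[pose$t_s >= window[1] & pose$t_s < window[2], ]
  }
  hh <- head_height(pose)
  p <- ggplot2::ggplot(hh, ggplot2::aes(.data$t_s, .data$h)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "session time (s)", y = "head height (1 - y)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = events$peak_s,
                                 linetype = "dashed", colour = "red")
  }
  p
}
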