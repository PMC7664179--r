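#' Bland-Altman plot of matched event pairs
#'
#' Mean of the two methods' event times against their difference, with
#' the bias and 95% limits of agreement drawn as horizontal lines.
#'
#' @param object A `matched_pairs` tibble (see [match_events()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.matched_pairs <- function(object, ...) {
  ba <- bland_altman(object)
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$t_ref + .data$t_test) / 2,
    y = .data$diff_s * 1000
  )) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = ba$bias_ms, linetype = "solid") +
    ggplot2::geom_hline(
      yintercept = c(ba$loa_low_ms, ba$loa_high_ms), linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Mean event time (s)",
      y = "Difference, test - reference (ms)",
      title = sprintf("Bland-Altman: bias %.1f ms, LoA [%.1f, %.1f] ms",
                      ba$bias_ms, ba$loa_low_ms, ba$loa_high_ms)
    ) +
    ggplot2::theme_minimal()
}

#' Plot trial channels with optional event overlay
#'
#' @param object A `gait_trial`.
#' @param channels Channel names to show (default: the detection
#'   channels of the left side plus left heel displacement inputs).
#' @param events Optional `event_series` to overlay as vertical lines.
#' @param ... Unused.
#' @return A ggplot faceted by channel.
#' @export
autoplot.gait_trial <- function(object, channels = NULL, events = NULL,
                                ...) {
  channels <- channels %||%
    intersect(c("H.ACC.Z.L", "H.GY.Z.L", "T.ACC.Z.L", "HEEL_L.X"),
              c(names(object$imu), names(object$markers)))
  long <- dplyr::bind_rows(lapply(channels, function(ch) {
    ts <- trial_channel(object, ch)
    tibble(time_s = ts$time_s, value = ts$value, channel = ch)
  }))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    ev <- as_tibble(events)
    p <- p + ggplot2::geom_vline(
      data = ev,
      ggplot2::aes(xintercept = .data$time_s, color = .data$kind),
      alpha = 0.4, linewidth = 0.3
    )
  }
  p
}

#' Stride-time series plot for two methods
#'
#' @param ref,test `event_series` objects.
#' @param kind Event kind defining strides.
#' @return A ggplot of stride time against stride start, by method.
#' @export
plot_stride_times <- function(ref, test, kind = "IC") {
  df <- dplyr::bind_rows(
    dplyr::mutate(stride_times(ref, kind = kind), method = "reference"),
    dplyr::mutate(stride_times(test, kind = kind), method = "test")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_start,
                                   y = .data$stride_s,
                                   color = .data$method)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(x = "Stride start (s)", y = "Stride time (s)") +
    ggplot2::theme_minimal()
}
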