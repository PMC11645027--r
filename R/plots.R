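#' Plot an IMU recording
#'
#' Facets the three acceleration channels and the pitch angular velocity
#' over time, with ground-truth transition events (when present) marked
#' as vertical dashed lines.
#'
#' @param object An [imu_recording()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.imu_recording <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("t", "acc_ml", "acc_ap", "acc_si", "gyr_pitch")],
    -"t",
    names_to = "channel", values_to = "value"
  )
  long$channel <- factor(long$channel,
    levels = c("acc_ml", "acc_ap", "acc_si", "gyr_pitch"),
    labels = c("ML accel (m/s²)", "AP accel (m/s²)",
               "SI accel (m/s²)", "Pitch ang. vel. (deg/s)")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL)
  ev <- ground_truth_events(object)
  if (!is.null(ev) && nrow(ev) > 0) {
    p <- p + ggplot2::geom_vline(
      data = ev, ggplot2::aes(xintercept = .data$time_s),
      linetype = "dashed", colour = "grey50", linewidth = 0.3
    )
  }
  p
}

#' Confusion-matrix heat map of an evaluation
#'
#' @param object An `ls_eval` from [evaluate_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ls_eval <- function(object, ...) {
  df <- as.data.frame(object$confusion_matrix)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("%s (accuracy %.2f)", object$model_family, object$accuracy),
      x = "Predicted class", y = "True class", fill = "Count"
    )
}

#' Segment overlay plot
#'
#' Plots the pitch angular-velocity trace with the detected transition
#' windows shaded by kind.
#'
#' @param recording A preprocessed [imu_recording()].
#' @param segments Segment tibble from [segment_recording()].
#' @return A ggplot object.
#' @export
plot_segments <- function(recording, segments) {
  segs <- segments[segments$kind %in% c("SiSt", "StSi"), ]
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = segs,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$kind),
      alpha = 0.25
    ) +
    ggplot2::geom_line(
      data = tibble::as_tibble(recording),
      ggplot2::aes(x = .data$t, y = .data$gyr_pitch),
      linewidth = 0.3
    ) +
    ggplot2::labs(x = "Time (s)", y = "Pitch angular velocity (deg/s)",
                  fill = "Transition")
}
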