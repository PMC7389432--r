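#' Plot normalized envelopes over a time span
#'
#' @param object An `envelope_set`.
#' @param from_s,to_s Time span to show, in seconds.
#' @param channels Channels to include (default: all ten).
#' @param ... Unused.
#' @return A ggplot with one facet per channel and the target-leg
#'   foot-floor-contact signal overlaid as a shaded swing band.
#' @export
autoplot.envelope_set <- function(object, from_s = 0, to_s = 5,
                                  channels = emg_channels(), ...) {
  fs <- attr(object, "sampling_rate")
  keep <- object$sample >= from_s * fs & object$sample < to_s * fs
  d <- as_tibble(object)[keep, c("sample", channels)]
  d$time_s <- d$sample / fs
  long <- tidyr::pivot_longer(d, dplyr::all_of(channels),
                              names_to = "channel", values_to = "envelope")
  long$channel <- factor(long$channel, levels = emg_channels())
  baso <- attr(object, "basographic")$FSW_L[keep]
  swing <- rle_tbl(baso)
  swing <- swing[swing$value == 1, , drop = FALSE]
  swing$xmin <- (swing$start + object$sample[keep][1]) / fs
  swing$xmax <- swing$xmin + swing$length / fs
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$envelope)) +
    ggplot2::geom_rect(data = swing,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
                       ymin = -Inf, ymax = Inf, alpha = 0.15,
                       inherit.aes = FALSE) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 2) +
    ggplot2::labs(x = "time (s)", y = "normalized envelope",
                  title = "sEMG envelopes",
                  subtitle = "shaded bands: left-leg swing phases")
}

#' Compare per-subject metrics of two studies
#'
#' Side-by-side bars of a chosen per-subject metric (accuracy or event
#' MAE) for, typically, the intra- and inter-subject protocols.
#'
#' @param a,b `gait_study` objects (e.g. intra and inter).
#' @param metric Column of [tidy.gait_study()] to compare.
#' @return A ggplot.
#' @export
plot_study_comparison <- function(a, b, metric = "test_accuracy") {
  d <- dplyr::bind_rows(
    dplyr::mutate(a$subjects, protocol = a$protocol),
    dplyr::mutate(b$subjects, protocol = b$protocol))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$subject,
                                  y = .data[[metric]],
                                  fill = .data$protocol)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "subject", y = metric,
                  title = sprintf("Per-subject %s by protocol", metric))
}

#' Plot predicted vs. ground-truth foot-floor-contact signals
#'
#' @param predicted,truth Binary 0/1 vectors on the same timeline.
#' @param sampling_rate Sampling rate in Hz.
#' @param from_s,to_s Time span to show, in seconds.
#' @return A ggplot of the two signals as step traces.
#' @export
plot_basographic <- function(predicted, truth, sampling_rate,
                             from_s = 0, to_s = 10) {
  idx <- seq(max(1, floor(from_s * sampling_rate) + 1),
             min(length(truth), ceiling(to_s * sampling_rate)))
  d <- tibble(time_s = rep((idx - 1) / sampling_rate, 2),
              value = c(truth[idx], predicted[idx] + 1.5),
              series = rep(c("ground truth", "predicted"),
                           each = length(idx)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$value,
                                  group = .data$series)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::scale_y_continuous(breaks = c(0.5, 2),
                                labels = c("ground truth", "predicted")) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Foot-floor-contact: predicted vs. ground truth",
                  subtitle = "low = stance, high = swing")
}
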