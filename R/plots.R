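# ggplot2 displays for results.

#' Plot per-fold accuracies of a cross-validation result
#'
#' @param object an `esn_cv`.
#' @param ... unused.
#' @return a ggplot: test (and train) accuracy per fold, with the mean test
#'   accuracy as a horizontal reference.
#' @export
autoplot.esn_cv <- function(object, ...) {
  f <- tidyr::pivot_longer(object$folds,
                           c("train_accuracy", "test_accuracy"),
                           names_to = "side", values_to = "accuracy")
  f$side <- sub("_accuracy", "", f$side)
  ggplot2::ggplot(f, ggplot2::aes(x = factor(.data$fold), y = .data$accuracy,
                                  fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = mean(object$folds$test_accuracy),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "fold", y = "accuracy",
                  title = sprintf("%s cross-validation", object$scheme)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a grid-search score surface
#'
#' @param object an `esn_grid` from [grid_search()].
#' @param ... unused.
#' @return a ggplot tile map of the mean score over the (leaking rate,
#'   spectral radius) grid, with the selected combination marked.
#' @export
autoplot.esn_grid <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$leaking_rate, y = .data$spectral_radius,
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$best, color = "red") +
    ggplot2::scale_fill_viridis_c(name = object$statistic) +
    ggplot2::labs(x = "leaking rate", y = "spectral radius") +
    ggplot2::theme_minimal()
}

#' Plot a smoothing curve
#'
#' @param curve tibble from [smoothing_curve()].
#' @return a ggplot of accuracy against smoothing window (0.5 s per output).
#' @export
plot_smoothing_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$window, y = .data$accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = curve$window,
                                labels = sprintf("%g s", curve$window * 0.5)) +
    ggplot2::labs(x = "smoothing window", y = "mean test accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a stretch of a labeled recording
#'
#' @param recording a `labeled_recording`.
#' @param from_s,to_s time window to display, seconds.
#' @return a ggplot of the channels with state shading.
#' @export
plot_recording <- function(recording, from_s = 0,
                           to_s = min(30, ncol(recording$signal) / recording$sampling_rate_hz)) {
  fs <- recording$sampling_rate_hz
  idx <- max(1, round(from_s * fs)):min(ncol(recording$signal), round(to_s * fs))
  df <- as_tibble(t(recording$signal[, idx, drop = FALSE])) %>%
    mutate(time_s = (idx - 1) / fs) %>%
    tidyr::pivot_longer(-"time_s", names_to = "channel", values_to = "uV")
  sched <- recording$schedule %>%
    filter(.data$end_s > from_s, .data$start_s < to_s, .data$state != "none")
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(data = sched,
                       ggplot2::aes(xmin = pmax(.data$start_s, from_s),
                                    xmax = pmin(.data$end_s, to_s),
                                    ymin = -Inf, ymax = Inf, fill = .data$state),
                       alpha = 0.15, inherit.aes = FALSE) +
    ggplot2::geom_line(ggplot2::aes(x = .data$time_s, y = .data$uV), linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "amplitude (uV)") +
    ggplot2::theme_minimal()
}
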