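#' Plot condition waveforms with cluster annotations
#'
#' Grand-average dilation curves per condition with a SEM ribbon and,
#' optionally, a bar marking each significant cluster along the time axis.
#'
#' @param grand_avg Tibble from [grand_average()].
#' @param clusters Optional [detect_clusters()] result.
#' @param window Optional summary window `c(start_ms, end_ms)` to shade.
#' @return A ggplot object.
#' @export
plot_waveforms <- function(grand_avg, clusters = NULL, window = NULL) {
  p <- ggplot2::ggplot(grand_avg,
                       ggplot2::aes(x = .data$rel_time_ms, y = .data$mean_mm,
                                    color = .data$condition, fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_mm - .data$sem_mm,
                                      ymax = .data$mean_mm + .data$sem_mm),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "Time from stimulus onset (ms)",
                  y = "Pupil dilation (mm)", color = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect", xmin = window[1], xmax = window[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.08)
  }
  if (!is.null(clusters) && nrow(clusters) > 0) {
    ymin <- min(grand_avg$mean_mm - grand_avg$sem_mm)
    p <- p + ggplot2::annotate("segment",
                               x = clusters$start_ms, xend = clusters$end_ms,
                               y = ymin, yend = ymin, linewidth = 1.5)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.pupil_clusters <- function(object, ...) {
  if (nrow(object) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no significant clusters") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(tibble::as_tibble(object)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start_ms, xend = .data$end_ms,
                                       y = factor(.data$cluster),
                                       yend = factor(.data$cluster)),
                          linewidth = 2) +
    ggplot2::labs(x = "Time from stimulus onset (ms)", y = "Cluster") +
    ggplot2::theme_minimal()
}

#' Plot per-subject dilation against a behavioral measure
#'
#' The scatterplot used for individual-differences results: one dot per
#' subject, with a least-squares line.
#'
#' @param measures Tibble with one row per subject.
#' @param x,y Column names (strings) to plot.
#' @return A ggplot object.
#' @export
plot_subject_scatter <- function(measures, x, y) {
  ggplot2::ggplot(measures, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "grey30") +
    ggplot2::theme_minimal()
}
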