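#' Spaghetti plot of per-islet percent traces
#'
#' One line per islet, integrated density as a percentage of the reference
#' time point (100 = unchanged).
#'
#' @param summary A `gsis_summary`.
#' @return A ggplot object.
#' @export
plot_traces <- function(summary) {
  po <- summary$percent_traces
  po$islet_id <- factor(po$islet_id)
  ggplot2::ggplot(po, ggplot2::aes(x = .data$time_point, y = .data$percent,
                                   group = .data$islet_id,
                                   colour = .data$islet_id)) +
    ggplot2::geom_line(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "time (min)",
                  y = sprintf("integrated density (%% of t%g)",
                              summary$reference_time)) +
    ggplot2::theme_minimal()
}

#' Size-response scatter
#'
#' Islet area (pixels, log scale) against the log ratio of end to
#' reference integrated density; the flat cloud expected when secretion is
#' size-independent.
#'
#' @param summary A `gsis_summary`.
#' @return A ggplot object.
#' @export
plot_size_response <- function(summary) {
  per <- summary$per_islet
  ggplot2::ggplot(per, ggplot2::aes(x = .data$area_px, y = .data$log10_ratio)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "islet area (px)",
                  y = sprintf("log10 ID(t%g) / ID(t%g)",
                              summary$end_time, summary$reference_time)) +
    ggplot2::theme_minimal()
}

#' Heterogeneity SEM comparison plot
#'
#' Per-experiment SEM of the islet percent responses for two groups
#' (e.g. culture wells vs pancreata).
#'
#' @param sem_a,sem_b Numeric vectors of per-experiment heterogeneity SEMs.
#' @param labels Group labels.
#' @return A ggplot object.
#' @export
plot_sem_comparison <- function(sem_a, sem_b,
                                labels = c("in vitro", "in vivo")) {
  df <- data.frame(
    group = factor(rep(labels, c(length(sem_a), length(sem_b))),
                   levels = labels),
    sem = c(sem_a, sem_b)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$sem)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "SEM of islet response (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
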