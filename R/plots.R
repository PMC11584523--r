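bin_label_ <- function(lo, hi) {
  ifelse(is.infinite(hi), sprintf(">= %g", lo), sprintf("%g-%g", lo, hi))
}

#' Plot a bottleneck-radius histogram
#'
#' @param histogram Output of [br_histogram()].
#' @return A ggplot.
#' @export
plot_br_histogram <- function(histogram) {
  histogram$bin <- factor(bin_label_(histogram$bin_lo, histogram$bin_hi),
                          levels = unique(bin_label_(histogram$bin_lo,
                                                     histogram$bin_hi)))
  p <- ggplot2::ggplot(histogram,
                       ggplot2::aes(x = .data$bin, y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "bottleneck radius (Å)", y = "frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  facets <- intersect(c("condition", "replicate_id", "supercluster_id"),
                      names(histogram))
  if (length(facets) > 0)
    p <- p + ggplot2::facet_wrap(facets)
  p
}

#' Plot an across-replicate dwell-duration histogram
#'
#' @param dwell Output of [dwell_histogram()].
#' @return A ggplot (mean bin mass with SD error bars per condition).
#' @export
plot_dwell_histogram <- function(dwell) {
  dwell$bin <- factor(bin_label_(dwell$bin_lo, dwell$bin_hi),
                      levels = unique(bin_label_(dwell$bin_lo, dwell$bin_hi)))
  ggplot2::ggplot(dwell, ggplot2::aes(x = .data$bin, y = .data$mean_frequency,
                                      fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$mean_frequency - .data$sd_frequency),
                   ymax = .data$mean_frequency + .data$sd_frequency),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3
    ) +
    ggplot2::labs(x = "open-state duration (ns)", y = "frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @export
autoplot.td_discovery <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$time, y = .data$mean_count,
                               colour = .data$condition,
                               fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min_count,
                                      ymax = .data$max_count),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (ns)", y = "distinct superclusters identified") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.td_comparison <- function(object, ...) {
  cells <- object$cells
  long <- bind_rows(
    tibble(supercluster_id = cells$supercluster_id, metric = cells$metric,
           condition = object$conditions[1], mean = cells$mean_a,
           sd = cells$sd_a, mark = ifelse(cells$significant, "*",
                                          ifelse(cells$untestable, "!", ""))),
    tibble(supercluster_id = cells$supercluster_id, metric = cells$metric,
           condition = object$conditions[2], mean = cells$mean_b,
           sd = cells$sd_b, mark = "")
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$supercluster_id),
                               y = .data$mean, fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3,
      na.rm = TRUE
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$mark,
                                    y = .data$mean + ifelse(is.na(.data$sd),
                                                            0, .data$sd)),
                       vjust = -0.4, na.rm = TRUE) +
    ggplot2::facet_wrap("metric", scales = "free_y") +
    ggplot2::labs(x = "supercluster", y = "replicate mean ± SD") +
    ggplot2::theme_minimal()
}

#' Plot bottleneck-radius time series
#'
#' @param series Output of [bottleneck_series()].
#' @return A ggplot, one panel per supercluster, lines per replicate.
#' @export
plot_bottleneck_series <- function(series) {
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$time, y = .data$bottleneck,
                               colour = .data$replicate_id)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$supercluster_id),
                        cols = ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = "time (ns)", y = "bottleneck radius (Å)") +
    ggplot2::theme_minimal()
}
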