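# Diagnostic figures for the sweep and metric objects.

#' @exportS3Method ggplot2::autoplot
autoplot.threshold_sweep <- function(object, ...) {
  thr <- selected_threshold(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$threshold, y = .data$retained)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(
      x = "log10 variance threshold", y = "genes retained",
      title = sprintf("Variance derivative sweep (selected %.2f)", thr)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.entropy_sweep <- function(object, ...) {
  sel <- attr(object, "selected_percentile")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$percentile, y = .data$entropy)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = sel, linetype = "dashed") +
    ggplot2::labs(
      x = "divergence percentile", y = "betweenness entropy (nats)",
      title = sprintf("Betweenness-entropy sweep (selected percentile %d)", sel)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.grn_panel <- function(object, ...) {
  long <- tidyr::pivot_longer(object$nodes, c("betweenness", "closeness", "eigenvector"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$degree, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "degree", y = NULL, title = "GRN centrality panel") +
    ggplot2::theme_minimal()
}

#' Mean neighbor degree against degree
#'
#' The three-phase shape of this curve (initial fall, assortative rise,
#' neutral plateau) summarizes degree mixing in the gene network.
#'
#' @param panel A `grn_panel`.
#' @return A ggplot object.
#' @export
plot_degree_assortativity <- function(panel) {
  ggplot2::ggplot(panel$knn,
                  ggplot2::aes(x = .data$degree, y = .data$mean_neighbor_degree)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "degree", y = "mean neighbor degree",
                  title = sprintf("Degree assortativity (r = %.3f)", panel$assortativity)) +
    ggplot2::theme_minimal()
}
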