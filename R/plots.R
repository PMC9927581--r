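#' @importFrom rlang .data
NULL

#' Plot the Calinski-Harabasz model-selection trace
#'
#' Line-and-point trace of the CH index against the number of clusters, the
#' selected k highlighted — the standard "optimal number of enterotypes"
#' panel.
#'
#' @param object An [enterotype()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.enterotype_fit <- function(object, ...) {
  tr <- object$trace
  best <- tr[tr$k == object$optimal_k, ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$k, y = .data$ch)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = best, colour = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = tr$k) +
    ggplot2::labs(x = "Number of enterotypes",
                  y = "Calinski-Harabasz index") +
    ggplot2::theme_minimal()
}

#' Ordination plot of a PCoA, optionally coloured by cluster
#'
#' @param object A [pcoa()] result.
#' @param clusters Optional clustering object or named label vector.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pcoa_result <- function(object, clusters = NULL, ...) {
  df <- tidy(object)
  pe <- round(100 * object$proportion_explained[1:2], 1)
  p <- if (!is.null(clusters)) {
    lab <- cluster_labels(clusters)[df$sample_id]
    df$cluster <- factor(lab)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2,
                                     colour = .data$cluster))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2))
  }
  p + ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::stat_ellipse(level = 0.95, linetype = 2, na.rm = TRUE) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", pe[1]),
                  y = sprintf("PCo2 (%.1f%%)", pe[2])) +
    ggplot2::theme_minimal()
}

#' Microbe-trait correlation heatmap
#'
#' Tile heatmap of Spearman rho for each genus-trait pair with significance
#' stars (* p < 0.05, ** p < 0.01).
#'
#' @param corr A [trait_correlations()] result.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(corr) {
  stopifnot(inherits(corr, "correlation_matrix"))
  df <- tibble::as_tibble(corr)
  df$stars <- dplyr::case_when(df$sig_01 ~ "**", df$sig_05 ~ "*",
                               TRUE ~ "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$genus,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
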