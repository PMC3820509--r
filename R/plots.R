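#' Scree plot of an ensemble PCA
#'
#' @param object an `ens_pca`.
#' @param k number of components to show (default 10).
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ens_pca <- function(object, k = 10L, ...) {
  d <- head(tidy(object), k)
  ggplot2::ggplot(d, ggplot2::aes(.data$pc, .data$var_percent)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", .data$cum_percent)),
      vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Principal component", y = "% of total variance",
                  title = "Eigenvalue spectrum") +
    ggplot2::theme_minimal()
}

#' Conformer plot: frames projected onto PC1/PC2
#'
#' @param object a `conformer_clusters`.
#' @param projections the projections tibble the clustering was built from.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.conformer_clusters <- function(object, projections, ...) {
  d <- dplyr::left_join(projections, object$labels,
                        by = intersect(c("frame", "label"),
                                       names(projections)))
  ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                  colour = factor(.data$cluster))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "PC1 (Å)", y = "PC2 (Å)",
                  colour = "cluster", title = "Conformer plot") +
    ggplot2::theme_minimal()
}

#' Residue-residue correlation map
#'
#' Renders the DCCM with the conventional thresholded scale: pink for
#' correlations in [-1, -0.5], white across (-0.5, 0.5), cyan for [0.5, 1].
#'
#' @param object a `dccm_matrix`.
#' @param threshold magnitude below which correlations are blanked
#'   (default 0.5).
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dccm_matrix <- function(object, threshold = 0.5, ...) {
  n <- nrow(object$matrix)
  d <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  d$correlation <- as.vector(t(object$matrix))
  d$shown <- ifelse(abs(d$correlation) >= threshold, d$correlation, 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$i, .data$j, fill = .data$shown)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "pink", mid = "white",
                                  high = "cyan3", limits = c(-1, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Residue", y = "Residue", fill = "C_ij",
                  title = "Dynamical cross-correlation") +
    ggplot2::theme_minimal()
}

#' Contact-event activity curve
#'
#' @param object an `event_series`.
#' @param segments optional tibble from [segment_by_activity()]; boundaries
#'   are drawn as dashed lines.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.event_series <- function(object, segments = NULL, ...) {
  d <- object$events |>
    tidyr::pivot_longer(c("formation", "breaking", "total"),
                        names_to = "type", values_to = "count")
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$frame, .data$count,
                                       colour = .data$type)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_line(data = object$events,
                       ggplot2::aes(.data$frame, .data$activity),
                       colour = "black", inherit.aes = FALSE) +
    ggplot2::scale_colour_manual(values = c(formation = "forestgreen",
                                            breaking = "firebrick",
                                            total = "grey60")) +
    ggplot2::labs(x = "Frame", y = "Events",
                  title = "Contact formation/breaking activity") +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments) > 1L)
    p <- p + ggplot2::geom_vline(xintercept = segments$boundary[-1L],
                                 linetype = "dashed", colour = "grey40")
  p
}
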