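#' Plot a 2-D cell map colored by cluster
#'
#' @param coords cells x 2 coordinate matrix from [project_2d()].
#' @param labels per-cell cluster labels (0 = noise).
#' @return a ggplot.
#' @export
plot_cell_map <- function(coords, labels) {
  df <- tibble(
    x = coords[, 1], y = coords[, 2],
    cluster = factor(ifelse(labels == 0, "noise", as.character(labels)))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, color = .data$cluster)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", color = "cluster") +
    ggplot2::theme_minimal()
}

#' @method autoplot kdist_curve
#' @export
autoplot.kdist_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$rank, .data$kdist)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$epsilon, linetype = "dashed") +
    ggplot2::labs(
      x = "cells (sorted)", y = sprintf("%dth nearest distance", object$k),
      title = sprintf("elbow epsilon = %.3g%s", object$epsilon,
                      if (object$weak) " (weak)" else "")
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot ae_model
#' @export
autoplot.ae_model <- function(object, ...) {
  ggplot2::ggplot(object$loss_trace, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' @method autoplot category_result
#' @export
autoplot.category_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"label" %in% names(df)) df$label <- "all"
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$score)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "program score") +
    ggplot2::theme_minimal()
}

#' Plot cluster-by-group composition
#'
#' @param composition tibble from [composition_table()].
#' @return a stacked-bar ggplot of cluster proportions per group.
#' @export
plot_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(.data$group, .data$proportion,
                               fill = .data$cluster)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of group", fill = "cluster") +
    ggplot2::theme_minimal()
}
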