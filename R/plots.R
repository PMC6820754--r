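# ggplot2 views of connectomes, networks and metrics.

#' @export
autoplot.connectome <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = target, y = source,
                                   fill = weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(title = paste0("Connectome (", object$weight_kind, ")"),
                  x = "target node", y = "source node",
                  fill = object$weight_kind) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.significant_network <- function(object, ...) {
  if (!nrow(object$edges)) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "Empty significant network") +
             ggplot2::theme_void())
  }
  # nodes on a circle; arrows from source to target, width by |t|
  nodes <- object$nodes
  theta <- 2 * pi * seq_along(nodes) / length(nodes)
  layout <- tibble::tibble(node = nodes, x = cos(theta), y = sin(theta))
  e <- object$edges
  e$x0 <- layout$x[match(e$source, layout$node)]
  e$y0 <- layout$y[match(e$source, layout$node)]
  e$x1 <- layout$x[match(e$target, layout$node)]
  e$y1 <- layout$y[match(e$target, layout$node)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = e,
                          ggplot2::aes(x = x0, y = y0,
                                       xend = x1, yend = y1,
                                       linewidth = abs(t)),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          alpha = 0.6, color = "grey30") +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(x = x, y = y), size = 3) +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(x = 1.12 * x, y = 1.12 * y,
                                    label = node), size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Significant network: %d edges, %d nodes",
                                  nrow(e), length(nodes)),
                  linewidth = "|t|") +
    ggplot2::theme_void()
}

#' Group distributions of the per-subject graph metrics
#'
#' @param subjects The `subjects` tibble of a `pipeline_report` (must carry
#'   `group` and metric columns).
#' @param metrics Which metric columns to plot.
#' @return A ggplot object.
#' @export
plot_metric_distributions <- function(subjects,
                                      metrics = c("swp", "efficiency", "cpl")) {
  metrics <- intersect(metrics, names(subjects))
  stopifnot(length(metrics) >= 1, "group" %in% names(subjects))
  long <- do.call(rbind, lapply(metrics, function(m) {
    tibble::tibble(group = subjects$group, metric = m, value = subjects[[m]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = group, y = value,
                                     fill = group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 1, alpha = 0.7) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

utils::globalVariables(c("target", "source", "weight", "x0", "y0",
                         "x1", "y1", "t", "x", "y", "node", "group",
                         "value", "metric"))
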