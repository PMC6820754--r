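# broom-style tidiers for the result objects.

#' Tidy an edge statistic map into a long edge table
#'
#' @param x An `edge_stat_map`.
#' @param ... Unused.
#' @return Tibble with 0-based `source`, `target`, `t`, `p`, one row per
#'   directed edge.
#' @export
tidy.edge_stat_map <- function(x, ...) {
  n <- nrow(x$t)
  idx <- which(row(x$t) != col(x$t), arr.ind = TRUE)
  out <- tibble::tibble(
    source = as.integer(idx[, 1] - 1L),
    target = as.integer(idx[, 2] - 1L),
    t = x$t[idx],
    p = x$p[idx]
  )
  out[order(out$source, out$target), ]
}

#' @export
glance.edge_stat_map <- function(x, ...) {
  tibble::tibble(
    test_kind = x$test_kind,
    n_nodes = nrow(x$t),
    n_edges_tested = sum(!is.na(x$p)),
    n_permutations = x$n_permutations,
    min_p = min(x$p, na.rm = TRUE)
  )
}

#' @export
tidy.significant_network <- function(x, ...) {
  x$edges
}

#' @export
glance.significant_network <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x$edges),
    n_nodes = length(x$nodes),
    n_nodes_total = x$n_nodes_total,
    alpha_q = x$alpha_q,
    density = network_density(x$n_nodes_total, nrow(x$edges))
  )
}

#' @export
tidy.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  idx <- which(row(x$weights) != col(x$weights), arr.ind = TRUE)
  out <- tibble::tibble(
    source = x$nodes[idx[, 1]],
    target = x$nodes[idx[, 2]],
    weight = x$weights[idx]
  )
  out[order(out$source, out$target), ]
}

#' @export
glance.pipeline_report <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$subjects),
    n_edges_control = nrow(x$network_control$edges),
    n_edges_patient = nrow(x$network_patient$edges),
    n_edges_difference = nrow(x$network_difference$edges),
    fdr_q = x$manifest$parameters$fdr_q,
    seed = x$manifest$parameters$seed
  )
}
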