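# Weighted directed graph characterization. Shortest paths go through
# igraph with edge length = 1 / weight; everything else is computed here.

weights_to_igraph <- function(w) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (any(w < 0)) stop("weights must be non-negative (got negative entries)")
  len <- w
  len[w > 0] <- 1 / w[w > 0]
  len[w == 0] <- 0
  igraph::graph_from_adjacency_matrix(len, mode = "directed", weighted = TRUE,
                                      diag = FALSE)
}

graph_distances <- function(w) {
  n <- nrow(w)
  if (n == 0) return(matrix(numeric(0), 0, 0))
  g <- weights_to_igraph(w)
  d <- igraph::distances(g, mode = "out", weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")
  d[seq_len(n), seq_len(n), drop = FALSE]
}

#' Node strength of a significant network
#'
#' Sums the absolute weights (t-values) of all edges incident to each node,
#' in-edges and out-edges alike. Nodes the network does not touch get
#' strength zero.
#'
#' @param net A `significant_network`.
#' @return Numeric vector of length `n_nodes_total`, named by 0-based node
#'   id.
#' @export
node_strength <- function(net) {
  stopifnot(inherits(net, "significant_network"))
  s <- numeric(net$n_nodes_total)
  names(s) <- as.character(seq_len(net$n_nodes_total) - 1L)
  if (nrow(net$edges)) {
    for (k in seq_len(nrow(net$edges))) {
      w <- abs(net$edges$t[k])
      s[net$edges$source[k] + 1L] <- s[net$edges$source[k] + 1L] + w
      s[net$edges$target[k] + 1L] <- s[net$edges$target[k] + 1L] + w
    }
  }
  s
}

#' Network density over unordered node pairs
#'
#' Fraction of present connections to possible connections,
#' `n_edges / (n * (n - 1) / 2)`. The denominator counts unordered pairs
#' of the full node set (all potential network sites, not just touched
#' nodes), and the value is reported to 4 decimals.
#'
#' @param n_nodes_total Total number of potential nodes (>= 2).
#' @param n_edges Number of edges in the network.
#' @param digits Decimals to report (default 4).
#' @return Density (rounded).
#' @examples
#' network_density(863, 892)   # 0.0024
#' network_density(863, 441)   # 0.0012
#' @export
network_density <- function(n_nodes_total, n_edges, digits = 4) {
  stopifnot(n_nodes_total >= 2, n_edges >= 0)
  round(n_edges / (n_nodes_total * (n_nodes_total - 1) / 2), digits)
}

#' Global efficiency of a weighted directed graph
#'
#' Average inverse shortest-path length over ordered node pairs, with edge
#' length `1 / weight` and `1 / Inf = 0` for disconnected pairs.
#'
#' @param weights Non-negative square weight matrix (0 = no edge).
#' @return Efficiency in `[0, Inf)`.
#' @export
global_efficiency <- function(weights) {
  n <- nrow(weights)
  if (n < 2) return(0)
  d <- graph_distances(weights)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic path length of a weighted directed graph
#'
#' Mean shortest-path distance (edge length `1 / weight`) over ordered node
#' pairs with a finite path; the number of unreachable pairs is attached as
#' attribute `n_infinite`.
#'
#' @param weights Non-negative square weight matrix.
#' @return Mean finite distance, with attribute `n_infinite`.
#' @export
characteristic_path_length <- function(weights) {
  n <- nrow(weights)
  stopifnot(n >= 2)
  d <- graph_distances(weights)
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  if (!length(finite)) stop("no finite pair distances: graph fully disconnected")
  structure(mean(finite), n_infinite = sum(!is.finite(off)))
}

# Onnela weighted clustering coefficient on an undirected weight matrix
# (weights scaled by their maximum); mean over nodes with degree >= 2.
weighted_clustering <- function(w_und) {
  n <- nrow(w_und)
  mx <- max(w_und)
  if (mx == 0) return(0)
  wh <- (w_und / mx)^(1 / 3)
  k <- rowSums(w_und > 0)
  cyc <- diag(wh %*% wh %*% wh)
  ci <- ifelse(k >= 2, cyc / (k * (k - 1)), NA)
  if (all(is.na(ci))) return(0)
  mean(ci, na.rm = TRUE)
}

swp_from_deltas <- function(delta_c, delta_l) {
  dc <- min(1, max(0, delta_c))
  dl <- min(1, max(0, delta_l))
  1 - sqrt((dc^2 + dl^2) / 2)
}

safe_delta <- function(num, den) {
  if (abs(den) < 1e-12) return(if (num <= 0) 0 else 1)
  num / den
}

# Undirected surrogate graphs sharing the observed weight multiset:
# random = weights on uniformly random distinct pairs; lattice = weights
# sorted onto ring positions, strongest nearest the diagonal.
swp_null_graphs <- function(w_und) {
  n <- nrow(w_und)
  idx <- which(upper.tri(w_und) & w_und > 0)
  wts <- sort(w_und[idx])   # canonical order: nulls invariant to relabeling
  m <- length(wts)
  pairs_all <- which(upper.tri(w_und))
  random_graph <- function() {
    g <- matrix(0, n, n)
    pos <- sample(pairs_all, m)
    g[pos] <- sample(wts)
    g + t(g)
  }
  lattice_graph <- function() {
    ring <- expand.grid(i = seq_len(n), j = seq_len(n))
    ring <- ring[ring$i < ring$j, ]
    dist_ring <- pmin(ring$j - ring$i, n - (ring$j - ring$i))
    ord <- order(dist_ring, ring$i)
    slots <- ring[ord[seq_len(m)], ]
    g <- matrix(0, n, n)
    g[cbind(slots$i, slots$j)] <- sort(wts, decreasing = TRUE)
    g + t(g)
  }
  list(random = random_graph, lattice = lattice_graph)
}

#' Small-world propensity of a weighted network
#'
#' A `[0, 1]` index of how strongly a network combines the high clustering
#' of a lattice with the short paths of a random graph:
#' `SWP = 1 - sqrt((dC^2 + dL^2) / 2)` where
#' `dC = (C_latt - C_obs) / (C_latt - C_rand)` and
#' `dL = (L_obs - L_rand) / (L_latt - L_rand)`, each clipped to `[0, 1]`.
#' Clustering is the Onnela weighted coefficient on the symmetrized (max of
#' the two directions) graph; L is the weighted characteristic path length.
#' Null graphs preserve the node count and weight multiset: a ring lattice
#' with the strongest weights nearest the diagonal, and `n_random` uniform
#' rewirings (averaged).
#'
#' @param weights Non-negative square weight matrix (directed allowed; it is
#'   symmetrized by the elementwise maximum).
#' @param seed Integer seed for the random nulls.
#' @param n_random Number of random null graphs.
#' @return SWP in `[0, 1]`, with attributes `delta_c` and `delta_l`.
#' @export
small_worldness_propensity <- function(weights, seed = 1L, n_random = 50) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (any(weights < 0)) stop("weights must be non-negative")
  w <- pmax(weights, t(weights))
  diag(w) <- 0
  if (sum(w > 0) < 2) stop("too few edges for small-world structure")
  c_obs <- weighted_clustering(w)
  l_obs <- as.numeric(characteristic_path_length(w))
  nulls <- swp_null_graphs(w)
  g_latt <- nulls$lattice()
  c_latt <- weighted_clustering(g_latt)
  l_latt <- as.numeric(characteristic_path_length(g_latt))
  withr_seed(seed, {
    c_rand <- l_rand <- numeric(n_random)
    for (r in seq_len(n_random)) {
      g <- nulls$random()
      c_rand[r] <- weighted_clustering(g)
      d <- graph_distances(g)
      off <- d[row(d) != col(d)]
      fin <- off[is.finite(off)]
      l_rand[r] <- if (length(fin)) mean(fin) else NA
    }
  })
  c_rand <- mean(c_rand)
  l_rand <- mean(l_rand, na.rm = TRUE)
  if (abs(c_latt - c_rand) < 1e-12 && abs(l_latt - l_rand) < 1e-12 &&
      abs(c_latt - c_obs) < 1e-12 && abs(l_obs - l_rand) < 1e-12) {
    stop("degenerate nulls: lattice and random graphs are indistinguishable ",
         "from the observed network (C_latt = C_rand = ", signif(c_latt, 6),
         ", L_latt = L_rand = ", signif(l_latt, 6),
         "); SWP carries no information for this graph")
  }
  dc <- safe_delta(c_latt - c_obs, c_latt - c_rand)
  dl <- safe_delta(l_obs - l_rand, l_latt - l_rand)
  structure(swp_from_deltas(dc, dl),
            delta_c = min(1, max(0, dc)), delta_l = min(1, max(0, dl)))
}

#' Graph metrics of one subject's connectome on a significant-network mask
#'
#' Restricts the subject's z-scored weights to the masked edges (typically
#' the union of the group-level significant networks), clips any negative
#' masked weights to a small positive epsilon so `1/weight` lengths exist,
#' and computes SWP, global efficiency, characteristic path length and node
#' strengths. Density is a group-level quantity and is not computed here.
#'
#' @param connectome A z-scored `connectome`.
#' @param edge_mask Logical matrix of the same shape.
#' @param seed Seed for the SWP nulls.
#' @param epsilon Replacement for non-positive masked weights.
#' @return One-row tibble: `swp`, `efficiency`, `cpl`, `n_edges`, and
#'   `strengths` (list column).
#' @export
subject_graph_metrics <- function(connectome, edge_mask, seed = 1L,
                                  epsilon = 1e-6) {
  stopifnot(inherits(connectome, "connectome"), is.logical(edge_mask),
            all(dim(edge_mask) == dim(connectome$weights)))
  mask <- edge_mask
  diag(mask) <- FALSE
  if (!any(mask)) stop("empty edge mask: no network to characterize")
  w <- matrix(0, nrow(mask), ncol(mask))
  vals <- connectome$weights[mask]
  n_clipped <- sum(vals <= 0)
  vals[vals <= 0] <- epsilon
  w[mask] <- vals
  strengths <- rowSums(abs(w)) + colSums(abs(w))
  tibble::tibble(
    swp = as.numeric(small_worldness_propensity(w, seed = seed)),
    efficiency = global_efficiency(w),
    cpl = as.numeric(characteristic_path_length(w)),
    n_edges = sum(mask),
    n_clipped = n_clipped,
    strengths = list(strengths)
  )
}

#' Mann-Whitney comparison of a graph metric between groups
#'
#' Two-sided Mann-Whitney U test of `values_a` vs `values_b`: exact when
#' both groups have <= 8 subjects and no ties, otherwise the normal
#' approximation with tie correction. Reports both the raw U and the
#' standardized statistic `|z|` (the scale many packages print).
#'
#' @param values_a,values_b Numeric vectors (>= 2 each).
#' @param metric Optional metric name carried into the output.
#' @return One-row tibble: `metric`, `u`, `u_standardized`, `p`, `mean_a`,
#'   `mean_b`.
#' @export
compare_group_metrics <- function(values_a, values_b, metric = NA_character_) {
  n1 <- length(values_a)
  n2 <- length(values_b)
  stopifnot(n1 >= 2, n2 >= 2)
  ranks <- rank(c(values_a, values_b))
  u <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(values_a, values_b))
  has_ties <- any(ties > 1)
  if (all(c(values_a, values_b) == values_a[1])) {
    return(tibble::tibble(metric = metric, u = n1 * n2 / 2, u_standardized = 0,
                          p = 1, mean_a = mean(values_a), mean_b = mean(values_b)))
  }
  exact <- n1 <= 8 && n2 <= 8 && !has_ties
  p <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = FALSE)$p.value
  )
  N <- n1 + n2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  z <- if (sigma > 0) (u - n1 * n2 / 2) / sigma else 0
  tibble::tibble(metric = metric, u = u, u_standardized = abs(z), p = p,
                 mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Pearson correlation of a network metric with a behavioral score
#'
#' @param metric,score Numeric vectors of equal length (n >= 3), neither
#'   constant.
#' @param metric_name,score_name Optional labels carried into the output.
#' @return One-row tibble: `metric`, `score`, `r`, `p`, `n`.
#' @export
correlate_metrics_with_scores <- function(metric, score,
                                          metric_name = NA_character_,
                                          score_name = NA_character_) {
  stopifnot(length(metric) == length(score), length(metric) >= 3)
  if (sd(metric) == 0 || sd(score) == 0) {
    stop("constant vector: Pearson correlation undefined")
  }
  ct <- cor.test(metric, score, method = "pearson")
  n_obs <- length(metric)
  tibble::tibble(metric = metric_name, score = score_name,
                 r = unname(ct$estimate), p = ct$p.value, n = n_obs)
}
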