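# Edge-wise permutation statistics on stacks of connectomes.
#
# Connectome stacks are flattened to a subjects x edges matrix over the
# off-diagonal cells; all permutation nulls are computed by matrix algebra
# (the sum of squares is invariant under sign flips, and group sums under
# label permutation), so 5000 permutations over thousands of edges stay
# cheap.


# count, for each observed |t|, how many null |t| values are >= it
count_null_ge <- function(t_obs_abs, Tp, pooled, count_ge) {
  if (pooled) {
    v <- sort(abs(as.numeric(Tp)))
    count_ge + (length(v) - findInterval(t_obs_abs - 1e-12, v))
  } else {
    count_ge + colSums(abs(Tp) >=
                         matrix(t_obs_abs, nrow(Tp), length(t_obs_abs),
                                byrow = TRUE) - 1e-12)
  }
}

stack_offdiag <- function(connectomes) {
  n <- nrow(connectomes[[1]]$weights)
  off <- which(row(diag(n)) != col(diag(n)))
  X <- t(vapply(connectomes, function(cn) cn$weights[off], numeric(length(off))))
  list(X = X, off = off, n_nodes = n)
}

edge_stat_map <- function(t_mat, p_mat, n_permutations, test_kind) {
  diag(t_mat) <- 0
  diag(p_mat) <- NA_real_
  structure(list(t = t_mat, p = p_mat,
                 n_permutations = as.integer(n_permutations),
                 test_kind = test_kind),
            class = "edge_stat_map")
}

#' @export
print.edge_stat_map <- function(x, ...) {
  cat("<edge_stat_map> ", x$test_kind, " test over ", nrow(x$t), " nodes (",
      sum(!is.na(x$p)), " edges), ", x$n_permutations, " permutations\n",
      sep = "")
  invisible(x)
}

#' Within-group network detection by sign-flip permutation
#'
#' For every directed edge, tests the subjects' z-scored weights against
#' zero with a one-sample t statistic; the two-sided p-value comes from a
#' sign-flipping null in which each subject's value is randomly negated
#' (valid under symmetry of the null distribution about zero). The observed
#' statistic is included in the null count, so p never reaches zero.
#'
#' @param connectomes List of z-scored `connectome` objects, one per subject.
#' @param n_permutations Number of random sign assignments.
#' @param seed Integer seed.
#' @param flip_scope `"subject"` (default: one sign per subject per
#'   permutation) or `"cell"` (independent sign per subject and edge).
#' @param exact Enumerate all `2^n` per-subject sign patterns instead of
#'   sampling (subject scope only, small n); p is then the exact fraction of
#'   patterns at least as extreme, with no add-one correction.
#' @param null_pool `"pooled"` (default): each edge's p-value is computed
#'   against the permutation null pooled over all edges, giving p resolution
#'   `1/(n_permutations * n_edges + 1)` — required for step-up FDR at small q
#'   over many edges, and valid because z-scored edges are exchangeable
#'   under the null. `"per_edge"`: classical per-edge null with resolution
#'   `1/(n_permutations + 1)`.
#' @return An `edge_stat_map` with `t` and `p` matrices (diagonal `NA`).
#' @export
edgewise_one_sample_test <- function(connectomes, n_permutations = 5000,
                                     seed = 1L,
                                     flip_scope = c("subject", "cell"),
                                     exact = FALSE,
                                     null_pool = c("pooled", "per_edge")) {
  null_pool <- match.arg(null_pool)
  pooled <- null_pool == "pooled" && !exact
  flip_scope <- match.arg(flip_scope)
  stopifnot(length(connectomes) >= 3)
  if (exact && flip_scope != "subject") {
    stop("exact enumeration is defined for subject-level sign flips only")
  }
  if (exact && length(connectomes) > 16) {
    stop("exact enumeration limited to 16 subjects (2^n patterns)")
  }
  st <- stack_offdiag(connectomes)
  X <- st$X
  n <- nrow(X)
  m <- ncol(X)
  ss <- colSums(X^2)
  t_from_mean <- function(mu) {
    v <- (ss_rep - n * mu^2) / (n - 1)
    v[v < .Machine$double.eps] <- NA
    mu / sqrt(v / n)
  }
  mu_obs <- colMeans(X)
  ss_rep <- ss
  t_obs <- t_from_mean(mu_obs)
  degenerate <- is.na(t_obs)
  t_obs[degenerate] <- 0
  if (any(degenerate)) {
    message(sum(degenerate), " edge(s) with zero variance: t set to 0, p to 1")
  }
  count_ge <- numeric(m)
  n_null <- n_permutations
  if (exact) {
    n_patterns <- 2L^n
    S <- 2 * (outer(0:(n_patterns - 1), seq_len(n) - 1,
                    function(a, b) bitwAnd(a %/% 2^b, 1))) - 1
    M <- (S %*% X) / n
    ss_rep <- matrix(ss, n_patterns, m, byrow = TRUE)
    Tp <- t_from_mean(M)
    Tp[is.na(Tp)] <- 0
    count_ge <- colSums(abs(Tp) >=
                          matrix(abs(t_obs), n_patterns, m, byrow = TRUE) - 1e-12)
    p <- count_ge / n_patterns
    n_null <- n_patterns
  } else {
    withr_seed(seed, {
      chunk <- max(1L, min(n_permutations, floor(2.5e7 / m)))
      done <- 0L
      while (done < n_permutations) {
        P <- min(chunk, n_permutations - done)
        if (flip_scope == "subject") {
          S <- matrix(sample(c(-1, 1), P * n, replace = TRUE), P, n)
          M <- (S %*% X) / n
          ss_rep <- matrix(ss, P, m, byrow = TRUE)
          Tp <- t_from_mean(M)
        } else {
          Tp <- matrix(0, P, m)
          for (b in seq_len(P)) {
            Xs <- X * matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m)
            mu <- colMeans(Xs)
            ss_rep <- ss
            Tp[b, ] <- t_from_mean(mu)
          }
        }
        Tp[is.na(Tp)] <- 0
        count_ge <- count_null_ge(abs(t_obs), Tp, pooled, count_ge)
        done <- done + P
      }
    })
    n_null_stats <- if (pooled) n_permutations * m else n_permutations
    p <- (1 + count_ge) / (n_null_stats + 1)
  }
  p[degenerate] <- 1
  n_nodes <- st$n_nodes
  t_mat <- matrix(0, n_nodes, n_nodes)
  p_mat <- matrix(NA_real_, n_nodes, n_nodes)
  t_mat[st$off] <- t_obs
  p_mat[st$off] <- p
  edge_stat_map(t_mat, p_mat, n_null, "one_sample")
}

#' Between-group edge comparison by label permutation
#'
#' For every directed edge, an independent-samples (pooled-variance) t
#' statistic of group A minus group B, with a two-sided p-value from random
#' permutation of the group labels; optionally the permutation is combined
#' with per-subject sign flipping. Positive t means A > B.
#'
#' @param group_a,group_b Lists of `connectome` objects.
#' @param n_permutations Number of label permutations.
#' @param seed Integer seed.
#' @param sign_flip Also flip per-subject signs within each permutation.
#' @param null_pool `"pooled"` (default) or `"per_edge"`; see
#'   [edgewise_one_sample_test()].
#' @return An `edge_stat_map` (`test_kind = "two_sample"`).
#' @export
edgewise_two_sample_test <- function(group_a, group_b, n_permutations = 5000,
                                     seed = 1L, sign_flip = FALSE,
                                     null_pool = c("pooled", "per_edge")) {
  null_pool <- match.arg(null_pool)
  pooled <- null_pool == "pooled"
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  sa <- stack_offdiag(group_a)
  sb <- stack_offdiag(group_b)
  stopifnot(sa$n_nodes == sb$n_nodes)
  X <- rbind(sa$X, sb$X)
  na <- nrow(sa$X)
  nb <- nrow(sb$X)
  n <- na + nb
  m <- ncol(X)
  X2 <- X^2
  tot <- colSums(X)
  tot2 <- colSums(X2)
  t_stat <- function(sumA, ssA) {
    mA <- sumA / na
    mB <- (tot_rep - sumA) / nb
    sp2 <- (ssA - na * mA^2 + (tot2_rep - ssA) - nb * mB^2) / (n - 2)
    sp2[sp2 < .Machine$double.eps] <- NA
    (mA - mB) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  tot_rep <- tot
  tot2_rep <- tot2
  t_obs <- t_stat(colSums(X[seq_len(na), , drop = FALSE]),
                  colSums(X2[seq_len(na), , drop = FALSE]))
  degenerate <- is.na(t_obs)
  t_obs[degenerate] <- 0
  if (any(degenerate)) {
    message(sum(degenerate), " edge(s) with zero pooled variance: t = 0, p = 1")
  }
  count_ge <- numeric(m)
  withr_seed(seed, {
    chunk <- max(1L, min(n_permutations, floor(2.5e7 / m)))
    done <- 0L
    while (done < n_permutations) {
      P <- min(chunk, n_permutations - done)
      G <- matrix(0, P, n)
      for (b in seq_len(P)) G[b, sample.int(n, na)] <- 1
      if (sign_flip) {
        Tp <- matrix(0, P, m)
        for (b in seq_len(P)) {
          s <- sample(c(-1, 1), n, replace = TRUE)
          Xs <- X * s
          tot_rep <- colSums(Xs)
          tot2_rep <- tot2
          idx <- which(G[b, ] == 1)
          Tp[b, ] <- t_stat(colSums(Xs[idx, , drop = FALSE]),
                            colSums(X2[idx, , drop = FALSE]))
        }
      } else {
        tot_rep <- matrix(tot, P, m, byrow = TRUE)
        tot2_rep <- matrix(tot2, P, m, byrow = TRUE)
        Tp <- t_stat(G %*% X, G %*% X2)
      }
      Tp[is.na(Tp)] <- 0
      count_ge <- count_null_ge(abs(t_obs), Tp, pooled, count_ge)
      done <- done + P
    }
  })
  n_null_stats <- if (pooled) n_permutations * m else n_permutations
  p <- (1 + count_ge) / (n_null_stats + 1)
  p[degenerate] <- 1
  n_nodes <- sa$n_nodes
  t_mat <- matrix(0, n_nodes, n_nodes)
  p_mat <- matrix(NA_real_, n_nodes, n_nodes)
  t_mat[sa$off] <- t_obs
  p_mat[sa$off] <- p
  edge_stat_map(t_mat, p_mat, n_permutations, "two_sample")
}

#' Benjamini-Hochberg rejection mask over all directed edges
#'
#' Step-up FDR over the off-diagonal ordered node pairs of a p-value matrix.
#'
#' @param p Square p-value matrix (diagonal ignored; `NA` cells never
#'   rejected).
#' @param q FDR level.
#' @return Logical matrix of the same shape; `TRUE` where rejected.
#' @export
fdr_threshold <- function(p, q = 0.001) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p), q > 0, q < 1)
  pv <- p
  diag(pv) <- NA
  ok <- !is.na(pv)
  stopifnot(all(pv[ok] >= 0), all(pv[ok] <= 1))
  adj <- matrix(NA_real_, nrow(p), ncol(p))
  adj[ok] <- p.adjust(pv[ok], method = "BH")
  mask <- !is.na(adj) & adj <= q
  attr(mask, "p_adjusted") <- adj
  mask
}

#' Extract the significant directed network from a rejection mask
#'
#' @param stats An `edge_stat_map`.
#' @param mask Logical rejection matrix (e.g. from [fdr_threshold()]).
#' @param alpha_q The FDR level the mask was built at (stored on the result).
#' @param direction Keep `"both"` signs of the contrast (default), only
#'   `"positive"` t (e.g. patients > controls: hyper-connectivity), or only
#'   `"negative"` t.
#' @return A `significant_network`: list with `edges` (tibble of 0-based
#'   `source`, `target`, `t`, `p`, `p_adjusted`), `nodes` (0-based ids of
#'   touched nodes), `n_nodes_total` and `alpha_q`.
#' @export
extract_significant_network <- function(stats, mask, alpha_q = NA_real_,
                                        direction = c("both", "positive",
                                                      "negative")) {
  direction <- match.arg(direction)
  stopifnot(inherits(stats, "edge_stat_map"), is.logical(mask),
            all(dim(mask) == dim(stats$t)))
  mask <- switch(direction,
                 both = mask,
                 positive = mask & stats$t > 0,
                 negative = mask & stats$t < 0)
  adj <- attr(mask, "p_adjusted")
  idx <- which(mask, arr.ind = TRUE)
  edges <- tibble::tibble(
    source = as.integer(idx[, 1] - 1L),
    target = as.integer(idx[, 2] - 1L),
    t = stats$t[idx],
    p = stats$p[idx],
    p_adjusted = if (is.null(adj)) NA_real_ else adj[idx]
  )
  edges <- edges[order(edges$source, edges$target), ]
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$source, edges$target))),
                 n_nodes_total = nrow(mask),
                 alpha_q = alpha_q),
            class = "significant_network")
}

#' @export
print.significant_network <- function(x, ...) {
  cat("<significant_network> ", nrow(x$edges), " directed edges over ",
      length(x$nodes), " of ", x$n_nodes_total, " nodes",
      if (!is.na(x$alpha_q)) paste0(" (FDR q = ", x$alpha_q, ")"), "\n",
      sep = "")
  invisible(x)
}
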