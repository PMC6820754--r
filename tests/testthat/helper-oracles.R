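# Independent reference implementations used as oracles. Kept deliberately
# naive (table()-based entropies, dense triple-loop shortest paths) so they
# share no code with the package internals they check.

# brute-force PTE: explicit histogram tables in R, natural-log entropies
pte_oracle <- function(phase_x, phase_y, delay, bins) {
  bin_of <- function(ph) {
    i <- ceiling((ph + pi) / (2 * pi) * bins)
    pmin(pmax(i, 1), bins)
  }
  n <- length(phase_y)
  y_t <- bin_of(phase_y[1:(n - delay)])
  y_td <- bin_of(phase_y[(1 + delay):n])
  x_t <- bin_of(phase_x[1:(n - delay)])
  H <- function(...) {
    p <- as.numeric(table(paste(...)))
    p <- p / sum(p)
    -sum(p * log(p))
  }
  H(y_t, x_t) + H(y_td, y_t) - H(y_t) - H(y_td, y_t, x_t)
}

# Floyd-Warshall all-pairs shortest paths on lengths = 1/weight
floyd_warshall_lengths <- function(weights) {
  n <- nrow(weights)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && weights[i, j] > 0) d[i, j] <- 1 / weights[i, j]
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# stack of connectomes with i.i.d. N(0,1) off-diagonal weights
null_connectomes <- function(n_subjects, n_nodes, seed) {
  set.seed(seed)
  lapply(seq_len(n_subjects), function(i) {
    w <- matrix(rnorm(n_nodes^2), n_nodes, n_nodes)
    diag(w) <- 0
    connectome(w, "zscore")
  })
}

# connectome stack with a constant shift added at chosen edges
shifted_connectomes <- function(n_subjects, n_nodes, shift_idx, shift, seed) {
  cns <- null_connectomes(n_subjects, n_nodes, seed)
  lapply(cns, function(cn) {
    cn$weights[shift_idx] <- cn$weights[shift_idx] + shift
    cn
  })
}

# tiny significant_network builder for metric tests
toy_network <- function(edges_df, n_nodes_total, alpha_q = 0.05) {
  structure(list(
    edges = tibble::tibble(source = as.integer(edges_df$source),
                           target = as.integer(edges_df$target),
                           t = edges_df$t,
                           p = rep(0.001, nrow(edges_df)),
                           p_adjusted = rep(0.001, nrow(edges_df))),
    nodes = sort(unique(c(edges_df$source, edges_df$target))),
    n_nodes_total = n_nodes_total,
    alpha_q = alpha_q
  ), class = "significant_network")
}

# deterministic sine-plus-noise matrix for filter/phase tests
sine_matrix <- function(freqs_hz, fs, duration, noise_sd = 0, seed = 1) {
  set.seed(seed)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  m <- t(vapply(freqs_hz, function(f) {
    sin(2 * pi * f * t) + rnorm(length(t), 0, noise_sd)
  }, numeric(length(t))))
  m
}

rms <- function(x) sqrt(mean(x^2))
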