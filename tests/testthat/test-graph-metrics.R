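test_that("node strength sums |t| over incident edges, in and out", {
  star <- toy_network(data.frame(source = 0, target = 1:4, t = 1), 5)
  s <- node_strength(star)
  expect_equal(unname(s), c(4, 1, 1, 1, 1))

  single <- toy_network(data.frame(source = 0, target = 1, t = 3), 3)
  expect_equal(unname(node_strength(single)), c(3, 3, 0))

  empty <- toy_network(data.frame(source = integer(0), target = integer(0),
                                  t = numeric(0)), 4)
  expect_equal(unname(node_strength(empty)), rep(0, 4))
})

test_that("density uses unordered pairs and reproduces the worked values", {
  expect_equal(network_density(863, 892), 0.0024)
  expect_equal(network_density(863, 441), 0.0012)
  expect_equal(network_density(3, 3), 1.0)
})

test_that("efficiency and path length match hand computations", {
  # complete graph, unit weights
  k4 <- matrix(1, 4, 4)
  diag(k4) <- 0
  expect_equal(global_efficiency(k4), 1)
  expect_equal(as.numeric(characteristic_path_length(k4)), 1)

  # totally disconnected
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  expect_error(characteristic_path_length(matrix(0, 3, 3)), "disconnected")

  # 2 nodes, one directed edge of weight 2: d = 0.5 one way, Inf back
  w2 <- matrix(0, 2, 2)
  w2[1, 2] <- 2
  expect_equal(global_efficiency(w2), 1.0)
  cpl2 <- characteristic_path_length(w2)
  expect_equal(as.numeric(cpl2), 0.5)
  expect_equal(attr(cpl2, "n_infinite"), 1)

  # 3-node undirected chain: pair distances {1, 1, 2}
  ch <- matrix(0, 3, 3)
  ch[1, 2] <- ch[2, 1] <- ch[2, 3] <- ch[3, 2] <- 1
  expect_equal(as.numeric(characteristic_path_length(ch)), 4 / 3)

  # homogeneity: scaling weights by c divides CPL by c
  set.seed(2)
  w <- matrix(runif(36), 6, 6) * (matrix(runif(36), 6, 6) > 0.4)
  diag(w) <- 0
  w <- w + 0.01 * (matrix(1, 6, 6) - diag(6))   # ensure connected
  expect_equal(as.numeric(characteristic_path_length(3 * w)),
               as.numeric(characteristic_path_length(w)) / 3,
               tolerance = 1e-12)
})

test_that("shortest-path metrics agree with Floyd-Warshall on random graphs", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    w <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) > 0.5)
    diag(w) <- 0
    d_oracle <- floyd_warshall_lengths(w)
    off <- row(d_oracle) != col(d_oracle)
    inv <- 1 / d_oracle
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    expect_equal(global_efficiency(w), sum(inv) / (n * (n - 1)),
                 tolerance = 1e-12)
    fin <- d_oracle[off][is.finite(d_oracle[off])]
    if (length(fin)) {
      expect_equal(as.numeric(characteristic_path_length(w)), mean(fin),
                   tolerance = 1e-12)
    }
  }
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(17)
  for (rep in 1:10) {
    w <- matrix(runif(49), 7, 7) * (matrix(runif(49), 7, 7) > 0.6)
    diag(w) <- 0
    e0 <- global_efficiency(w)
    zero <- which(w == 0 & row(w) != col(w))
    w[sample(zero, 1)] <- runif(1, 0.2, 1)
    expect_gte(global_efficiency(w) + 1e-12, e0)
  }
})

test_that("SWP analytic cases and bounds hold", {
  expect_equal(ptenet:::swp_from_deltas(0, 0), 1, tolerance = 1e-12)
  expect_equal(ptenet:::swp_from_deltas(1, 1), 0, tolerance = 1e-12)
  expect_equal(ptenet:::swp_from_deltas(0, 1), 1 - sqrt(0.5),
               tolerance = 1e-12)
  # clipping keeps out-of-range deltas inside [0, 1]
  expect_equal(ptenet:::swp_from_deltas(-3, 0.5),
               ptenet:::swp_from_deltas(0, 0.5), tolerance = 1e-12)

  set.seed(4)
  for (rep in 1:5) {
    w <- matrix(runif(100), 10, 10) * (matrix(runif(100), 10, 10) > 0.5)
    diag(w) <- 0
    w <- pmax(w, t(w))
    if (sum(w > 0) < 4) next
    s <- small_worldness_propensity(w, seed = rep)
    expect_gte(s, 0)
    expect_lte(s, 1)
    # node relabeling leaves SWP unchanged
    perm <- sample(10)
    s2 <- small_worldness_propensity(w[perm, perm], seed = rep)
    expect_equal(as.numeric(s2), as.numeric(s), tolerance = 1e-12)
  }
})

test_that("subject metrics are deterministic and respect the mask", {
  set.seed(9)
  w <- matrix(rnorm(144), 12, 12)
  diag(w) <- 0
  cn <- connectome(w, "zscore")
  mask <- matrix(FALSE, 12, 12)
  idx <- cbind(c(1, 2, 3, 4, 5, 6, 7, 1), c(2, 3, 4, 5, 6, 7, 1, 5))
  mask[idx] <- TRUE
  m1 <- subject_graph_metrics(cn, mask, seed = 3)
  m2 <- subject_graph_metrics(cn, mask, seed = 3)
  expect_identical(m1[c("swp", "efficiency", "cpl")],
                   m2[c("swp", "efficiency", "cpl")])
  expect_true(m1$swp >= 0 && m1$swp <= 1)
  expect_true(is.finite(m1$efficiency) && is.finite(m1$cpl))
  expect_equal(m1$n_edges, 8)
  expect_error(subject_graph_metrics(cn, matrix(FALSE, 12, 12)), "empty")
})

test_that("Mann-Whitney comparison matches exact and degenerate cases", {
  cmp <- compare_group_metrics(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$p, 0.1)
  expect_equal(cmp$u, 0)

  same <- compare_group_metrics(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$u, 8)          # n1 * n2 / 2
  expect_equal(same$u_standardized, 0, tolerance = 1e-12)

  tied <- compare_group_metrics(rep(2, 4), rep(2, 5))
  expect_equal(tied$p, 1)

  # monotone transform of both groups preserves the rank statistic
  a <- c(0.1, 0.5, 0.9, 1.4)
  b <- c(0.3, 0.8, 1.1, 2.0)
  expect_equal(compare_group_metrics(exp(a), exp(b))$u,
               compare_group_metrics(a, b)$u)

  # standardized statistic matches the normal-approximation z
  set.seed(6)
  x <- rnorm(20)
  y <- rnorm(25) + 0.7
  cmp2 <- compare_group_metrics(x, y)
  u <- cmp2$u
  z <- abs((u - 20 * 25 / 2) / sqrt(20 * 25 * (20 + 25 + 1) / 12))
  expect_equal(cmp2$u_standardized, z, tolerance = 1e-10)
})

test_that("Pearson correlation matches hand computations", {
  expect_equal(correlate_metrics_with_scores(1:10, 2 * (1:10) + 1)$r, 1,
               tolerance = 1e-12)
  expect_equal(correlate_metrics_with_scores(c(1, 2, 3), c(6, 4, 5))$r, -0.5,
               tolerance = 1e-12)
  expect_error(correlate_metrics_with_scores(rep(1, 5), rnorm(5)),
               "constant")
  # ordering invariance
  set.seed(2)
  m <- rnorm(30)
  s <- rnorm(30)
  o <- sample(30)
  expect_equal(correlate_metrics_with_scores(m[o], s[o])$r,
               correlate_metrics_with_scores(m, s)$r, tolerance = 1e-12)
})
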