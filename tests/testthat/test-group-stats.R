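test_that("one-sample sign-flip test handles degenerate and signal edges", {
  cns <- null_connectomes(12, 6, seed = 2)
  # plant a strong consistent edge and a degenerate all-zero edge
  for (i in seq_along(cns)) {
    cns[[i]]$weights[1, 2] <- 3 + 0.1 * i
    cns[[i]]$weights[2, 1] <- 0
  }
  st <- suppressMessages(edgewise_one_sample_test(cns, 500, seed = 1))
  expect_equal(st$t[2, 1], 0)
  expect_equal(st$p[2, 1], 1)
  expect_true(is.na(st$p[1, 1]))
  expect_lt(st$p[1, 2], 0.01)
  expect_gt(st$t[1, 2], 10)

  # observed t matches the textbook one-sample statistic
  v <- vapply(cns, function(cn) cn$weights[1, 2], 0)
  expect_equal(st$t[1, 2], mean(v) / (sd(v) / sqrt(length(v))),
               tolerance = 1e-12)
})

test_that("exact sign-flip enumeration attains the minimal two-sided p", {
  cns <- null_connectomes(10, 4, seed = 3)
  for (i in seq_along(cns)) {
    cns[[i]]$weights[1, 2] <- abs(cns[[i]]$weights[1, 2]) + 0.5
  }
  st <- edgewise_one_sample_test(cns, exact = TRUE)
  # all-positive edge: only the two all-same-sign patterns are as extreme
  expect_equal(st$p[1, 2], 2 / 2^10)
})

test_that("two-sample test is antisymmetric in the group labels", {
  ca <- null_connectomes(8, 5, seed = 4)
  cb <- shifted_connectomes(8, 5, shift_idx = cbind(2, 3), shift = 1.5,
                            seed = 5)
  st_ab <- edgewise_two_sample_test(ca, cb, 300, seed = 9)
  st_ba <- edgewise_two_sample_test(cb, ca, 300, seed = 9)
  expect_equal(st_ab$t, -st_ba$t, tolerance = 1e-12)

  # identical groups: all t = 0, p = 1
  st_same <- suppressMessages(edgewise_two_sample_test(ca, ca, 300, seed = 1))
  expect_true(all(st_same$t == 0))
  expect_true(all(st_same$p[!is.na(st_same$p)] == 1))

  # observed t matches t.test with pooled variance
  va <- vapply(ca, function(cn) cn$weights[2, 3], 0)
  vb <- vapply(cb, function(cn) cn$weights[2, 3], 0)
  tt <- t.test(va, vb, var.equal = TRUE)
  expect_equal(st_ab$t[2, 3], unname(tt$statistic), tolerance = 1e-10)
})

test_that("a planted group shift is detected and order does not matter", {
  idx <- cbind(c(1, 3, 4), c(2, 1, 5))
  ca <- null_connectomes(15, 5, seed = 6)
  cb <- shifted_connectomes(15, 5, shift_idx = idx, shift = 2, seed = 7)
  st <- edgewise_two_sample_test(cb, ca, 1000, seed = 2)
  mask <- fdr_threshold(st$p, 0.01)
  expect_true(all(mask[idx]))
  expect_lt(sum(mask) - 3, 3)

  # subject order inside each group never changes the statistics; p-values
  # agree to permutation resolution (the null draw depends on the ordering)
  st2 <- edgewise_two_sample_test(cb[c(3:15, 1:2)], ca[15:1], 1000, seed = 2)
  expect_equal(st2$t, st$t, tolerance = 1e-12)
  expect_lt(max(abs(st2$p - st$p), na.rm = TRUE), 0.02)
})

test_that("permutation p-values are calibrated under the null", {
  res <- null_calibration_study(seed = 2, n_subjects = 15, n_nodes = 16,
                                n_permutations = 400)
  expect_gt(res$rate_one_sample, 0.02)
  expect_lt(res$rate_one_sample, 0.09)
  expect_gt(res$rate_two_sample, 0.02)
  expect_lt(res$rate_two_sample, 0.09)
  expect_lte(res$fdr_edges_one_sample, 1)
  expect_lte(res$fdr_edges_two_sample, 1)
})

test_that("BH step-up matches the hand-worked example and is monotone", {
  p <- matrix(1, 3, 3)
  p[cbind(c(1, 1, 2, 3), c(2, 3, 3, 1))] <- c(0.001, 0.02, 0.03, 0.04)
  p[cbind(c(2, 3), c(1, 2))] <- NA
  mask <- fdr_threshold(p, q = 0.05)
  # four finite p-values, largest 0.04 <= 4 * 0.05 / 4: all rejected
  expect_equal(sum(mask), 4)
  expect_false(any(mask & is.na(p)))

  all_one <- matrix(1, 4, 4)
  expect_equal(sum(fdr_threshold(all_one, 0.05)), 0)

  # shrinking q never adds rejections
  set.seed(8)
  pr <- matrix(runif(100), 10, 10)
  m1 <- fdr_threshold(pr, 0.2)
  m2 <- fdr_threshold(pr, 0.05)
  expect_true(all(m1[m2]))
})

test_that("significant-network extraction respects mask, direction, emptiness", {
  cns <- null_connectomes(10, 6, seed = 9)
  st <- suppressMessages(edgewise_one_sample_test(cns, 200, seed = 1))
  mask <- matrix(FALSE, 6, 6)
  net0 <- extract_significant_network(st, mask)
  expect_equal(nrow(net0$edges), 0)
  expect_length(net0$nodes, 0)

  mask[cbind(c(1, 2, 5), c(4, 6, 3))] <- TRUE
  net <- extract_significant_network(st, mask, alpha_q = 0.05)
  expect_equal(nrow(net$edges), 3)
  expect_setequal(net$nodes, 0:5)
  expect_equal(net$nodes, sort(unique(c(net$edges$source, net$edges$target))))

  pos <- extract_significant_network(st, mask, direction = "positive")
  expect_true(all(pos$edges$t > 0))
  neg <- extract_significant_network(st, mask, direction = "negative")
  expect_equal(nrow(pos$edges) + nrow(neg$edges), nrow(net$edges))
})

test_that("tidiers expose edge tables and summaries", {
  cns <- null_connectomes(8, 4, seed = 10)
  st <- suppressMessages(edgewise_one_sample_test(cns, 100, seed = 1))
  td <- tidy(st)
  expect_equal(nrow(td), 12)
  expect_named(td, c("source", "target", "t", "p"))
  gl <- glance(st)
  expect_equal(gl$n_edges_tested, 12)
  expect_equal(gl$test_kind, "one_sample")

  mask <- fdr_threshold(st$p, 0.5)
  net <- extract_significant_network(st, mask, 0.5)
  expect_equal(nrow(tidy(net)), nrow(net$edges))
  expect_equal(glance(net)$n_nodes_total, 4)
})
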