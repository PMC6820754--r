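unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}

test_that("instantaneous phase of a cosine is a wrapped ramp", {
  fs <- 600
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  x <- rbind(cos(2 * pi * 10 * t))
  ph <- instantaneous_phase(x, fs)
  expect_true(all(ph$phases > -pi & ph$phases <= pi))
  # unwrapped slope = 2*pi*f/fs rad/sample (away from the edges)
  core <- 200:4600
  slope <- mean(diff(unwrap_phase(ph$phases[1, ]))[core])
  expect_equal(slope, 2 * pi * 10 / fs, tolerance = 0.01 * 2 * pi * 10 / fs)

  # Hilbert linearity: sign flip shifts phase by pi (mod 2pi)
  ph_neg <- instantaneous_phase(-x, fs)
  d <- (ph_neg$phases - ph$phases) %% (2 * pi)
  expect_equal(max(abs(d[core] - pi)), 0, tolerance = 1e-6)

  expect_error(instantaneous_phase(matrix(1, 1, 100), fs), "constant")
})

test_that("delay estimation follows the phase sign-flip rule", {
  fs <- 600
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  ph <- instantaneous_phase(rbind(cos(2 * pi * 10 * t)), fs)
  expect_equal(estimate_delay(ph), 30)

  # independent uniform phases change sign between adjacent samples w.p. 1/2
  set.seed(1)
  pm <- structure(list(phases = matrix(runif(4 * 5000, -pi, pi), 4), fs = fs),
                  class = "phase_matrix")
  expect_lte(abs(estimate_delay(pm) - 2), 1)

  allpos <- structure(list(phases = matrix(abs(runif(200)) + 0.1, 1),
                           fs = fs), class = "phase_matrix")
  expect_error(estimate_delay(allpos), "sign")
})

test_that("bin-count rules reproduce their closed forms", {
  expect_identical(choose_bin_count(4800, "paper_fixed"), 49L)
  expect_identical(choose_bin_count(4800, "scott_style"), 56L)
  expect_identical(choose_bin_count(4800, "occupancy"), 16L)
  expect_error(choose_bin_count(50), "100")
})

test_that("PTE matches the brute-force histogram oracle on small alphabets", {
  set.seed(21)
  for (rep in 1:5) {
    px <- runif(64, -pi, pi)
    py <- runif(64, -pi, pi)
    for (delay in c(1, 3)) {
      got <- phase_transfer_entropy(px, py, pte_params(delay = delay,
                                                       bins = 4))
      expect_equal(got, pte_oracle(px, py, delay, 4), tolerance = 1e-12)
    }
  }
  # and at a realistic bin count
  px <- runif(500, -pi, pi)
  py <- runif(500, -pi, pi)
  expect_equal(phase_transfer_entropy(px, py, pte_params(delay = 5, bins = 49)),
               pte_oracle(px, py, 5, 49), tolerance = 1e-12)
})

test_that("PTE is invariant to a common phase shift before wrapping", {
  set.seed(3)
  spec <- make_coupling_spec(2, 1, strength_range = c(0.7, 0.7),
                             delay_range = c(10, 10), seed = 4)
  ts <- simulate_subject(spec, 4, 600, seed = 2)
  ph <- instantaneous_phase(ts$data, 600)$phases
  shift <- function(p, c) {
    q <- (p + c + pi) %% (2 * pi) - pi
    q[q <= -pi] <- pi
    q
  }
  p0 <- phase_transfer_entropy(ph[1, ], ph[2, ], pte_params(delay = 10,
                                                            bins = 12))
  # shift by an exact bin width so binned histograms rotate without mixing
  c0 <- 2 * pi / 12
  p1 <- phase_transfer_entropy(shift(ph[1, ], c0), shift(ph[2, ], c0),
                               pte_params(delay = 10, bins = 12))
  expect_equal(p0, p1, tolerance = 1e-12)
})

test_that("a pure delayed copy is detected in the correct direction", {
  set.seed(8)
  x <- as.numeric(arima.sim(list(ar = 0.95), 10000))
  delay <- 15
  y <- c(rnorm(delay), x[1:(10000 - delay)])
  phx <- instantaneous_phase(rbind(x), 600)$phases[1, ]
  phy <- instantaneous_phase(rbind(y), 600)$phases[1, ]
  prm <- pte_params(delay = delay, bins = 16)
  expect_gt(phase_transfer_entropy(phx, phy, prm),
            phase_transfer_entropy(phy, phx, prm))
})

test_that("independent series sit inside the Monte-Carlo null band", {
  set.seed(13)
  prm <- pte_params(delay = 5, bins = 16)
  null_d <- vapply(1:200, function(i) {
    px <- runif(1000, -pi, pi)
    py <- runif(1000, -pi, pi)
    phase_transfer_entropy(px, py, prm) - phase_transfer_entropy(py, px, prm)
  }, 0)
  band <- quantile(abs(null_d), 0.95)
  px <- runif(10000, -pi, pi)
  py <- runif(10000, -pi, pi)
  prm2 <- pte_params(delay = 5, bins = 16)
  d <- phase_transfer_entropy(px, py, prm2) -
    phase_transfer_entropy(py, px, prm2)
  expect_lt(abs(d), band)
})

test_that("adjacency matrices recover a planted chain and are equivariant", {
  spec <- make_coupling_spec(3, 2, seed = 1)
  spec$edges <- tibble::tibble(source = c(0L, 1L), target = c(1L, 2L),
                               strength = c(0.8, 0.8), delay = c(12L, 12L))
  ts <- simulate_subject(spec, 8, 600, seed = 6)
  ph <- instantaneous_phase(ts$data, 600)
  cn <- pte_adjacency(ph, pte_params(delay = 12, bins = 16))
  w <- cn$weights
  expect_equal(diag(w), rep(0, 3))
  expect_gt(w[1, 2], w[2, 1])
  expect_gt(w[2, 3], w[3, 2])

  # relabeling equivariance: permuting nodes permutes rows/cols consistently
  perm <- c(3, 1, 2)
  ph_perm <- structure(list(phases = ph$phases[perm, ], fs = 600),
                       class = "phase_matrix")
  cn_perm <- pte_adjacency(ph_perm, pte_params(delay = 12, bins = 16))
  expect_equal(cn_perm$weights, w[perm, perm], tolerance = 1e-12)
})

test_that("subject connectomes average epochs and z-score off-diagonals", {
  set.seed(5)
  mats <- lapply(1:4, function(i) {
    w <- matrix(runif(25), 5, 5)
    diag(w) <- 0
    connectome(w, "raw_pte")
  })
  z <- subject_connectome(mats)
  off <- z$weights[row(z$weights) != col(z$weights)]
  expect_equal(mean(off), 0, tolerance = 1e-10)
  expect_equal(sd(off), 1, tolerance = 1e-10)
  expect_equal(diag(z$weights), rep(0, 5))

  # identical epochs reduce to the z-score of the single matrix
  zz <- subject_connectome(list(mats[[1]], mats[[1]], mats[[1]]))
  w1 <- mats[[1]]$weights
  off1 <- w1[row(w1) != col(w1)]
  expected <- w1
  expected[row(w1) != col(w1)] <- (off1 - mean(off1)) / sd(off1)
  expect_equal(zz$weights, expected, tolerance = 1e-12)

  # averaging epochs shrinks the variance of i.i.d. entries
  single <- mats[[1]]$weights[1, 2]
  many <- replicate(50, {
    ms <- lapply(1:8, function(i) {
      w <- matrix(runif(25), 5, 5)
      diag(w) <- 0
      connectome(w, "raw_pte")
    })
    avg <- Reduce(`+`, lapply(ms, `[[`, "weights")) / 8
    avg[1, 2]
  })
  expect_lt(var(many), var(runif(400)))

  bad <- connectome(matrix(0, 4, 4), "raw_pte")
  expect_error(subject_connectome(list(mats[[1]], bad)), "shape")
})

test_that("phase-randomized surrogates keep amplitude spectra, kill coupling", {
  spec <- make_coupling_spec(2, 1, strength_range = c(0.9, 0.9),
                             delay_range = c(10, 10), seed = 2)
  ts <- simulate_subject(spec, 8, 600, seed = 3)
  sur <- phase_randomized_surrogate(ts$data, seed = 4)
  for (i in 1:2) {
    expect_equal(Mod(fft(sur[i, ])), Mod(fft(ts$data[i, ])),
                 tolerance = 1e-8)
  }
  expect_identical(phase_randomized_surrogate(ts$data, seed = 4), sur)
  expect_false(identical(phase_randomized_surrogate(ts$data, seed = 5), sur))

  # coupling asymmetry collapses into the null band on surrogates
  prm <- pte_params(delay = 10, bins = 16)
  ph <- instantaneous_phase(ts$data, 600)$phases
  d_obs <- phase_transfer_entropy(ph[1, ], ph[2, ], prm) -
    phase_transfer_entropy(ph[2, ], ph[1, ], prm)
  d_sur <- vapply(1:20, function(k) {
    s <- instantaneous_phase(phase_randomized_surrogate(ts$data, seed = k),
                             600)$phases
    phase_transfer_entropy(s[1, ], s[2, ], prm) -
      phase_transfer_entropy(s[2, ], s[1, ], prm)
  }, 0)
  expect_gt(abs(d_obs), quantile(abs(d_sur), 0.95))
})
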