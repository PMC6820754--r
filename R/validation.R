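# Simulation studies validating the estimator and the statistical pipeline
# on cohorts with known ground truth. These are the package's standing
# verification experiments; the test suite and the acceptance script both
# run them.

#' Direction-recovery study on planted coupled pairs
#'
#' Simulates independent two-node systems with one planted directed coupling
#' and asks, pair by pair, whether pTE assigns the planted direction
#' (`PTE(src -> tgt) > PTE(tgt -> src)`). Also runs the time-reversal sanity
#' check: reversing the epoch in time turns a delayed drive `y(t) = a x(t-d)`
#' into one where the reversed target leads, so the estimated direction must
#' flip; the flip rate is evaluated over the confidently-directed pairs
#' (absolute pTE asymmetry above the 95% band of a phase-randomized
#' surrogate null built from the same pairs).
#'
#' @param n_pairs Number of independent pairs.
#' @param strength Planted coupling strength.
#' @param delay_samples Planted delay, also used as the estimator delay.
#' @param duration,fs Per-pair recording length (seconds) and sampling rate.
#' @param seed Integer seed.
#' @param bins Histogram bins per axis; default sizes the joint histogram to
#'   the epoch length ([choose_bin_count()] `"occupancy"` mode).
#' @return A one-row tibble: `recovery_rate`, `flip_rate`, `n_pairs`,
#'   `n_confident`, `null_band`.
#' @export
direction_recovery_study <- function(n_pairs = 200, strength = 0.7,
                                     delay_samples = 20, duration = 8,
                                     fs = 600, seed = 1L, bins = NULL) {
  n_samples <- round(duration * fs)
  if (is.null(bins)) bins <- choose_bin_count(n_samples, "occupancy")
  params <- pte_params(delay = delay_samples, bins = bins)
  d_obs <- d_rev <- d_null <- numeric(n_pairs)
  base <- as.integer(seed) %% 100000L   # keep derived seeds under 2^31
  for (i in seq_len(n_pairs)) {
    spec <- make_coupling_spec(2, 1, strength_range = rep(strength, 2),
                               delay_range = rep(delay_samples, 2),
                               seed = base * 1000L + i)
    ts <- simulate_subject(spec, duration, fs, seed = base * 2000L + i)
    src <- spec$edges$source + 1L
    tgt <- spec$edges$target + 1L
    ph <- instantaneous_phase(ts$data, fs)$phases
    phr <- instantaneous_phase(ts$data[, n_samples:1, drop = FALSE],
                               fs)$phases
    sur <- phase_randomized_surrogate(ts$data, seed = base * 3000L + i)
    phs <- instantaneous_phase(sur, fs)$phases
    asym <- function(p) {
      phase_transfer_entropy(p[src, ], p[tgt, ], params) -
        phase_transfer_entropy(p[tgt, ], p[src, ], params)
    }
    d_obs[i] <- asym(ph)
    d_rev[i] <- asym(phr)
    d_null[i] <- asym(phs)
  }
  band <- stats::quantile(abs(d_null), 0.95, names = FALSE)
  confident <- abs(d_obs) > band
  tibble::tibble(
    recovery_rate = mean(d_obs > 0),
    flip_rate = mean(sign(d_rev[confident]) == -sign(d_obs[confident])),
    n_pairs = n_pairs,
    n_confident = sum(confident),
    null_band = band
  )
}

#' Build a two-group cohort with planted patient hyper-connectivity
#'
#' Both groups share a common coupling backbone; patients additionally carry
#' `n_extra` planted edges at `strength_extra` that controls lack entirely.
#' The planted patient-only edges form a random node-disjoint matching on
#' nodes the backbone does not touch. This isolation matters for measuring
#' edge-level recovery: whenever a planted edge shares a node with another
#' coupling, the co-driven nodes become genuinely correlated in patients
#' only, so true connectivity differences appear off the planted list and
#' precision stops being a property of the detector. (That behavior is a
#' property of the generative model, not an estimator failure.)
#'
#' @param n_nodes,n_common,n_extra Node count and edge counts. The backbone
#'   is drawn among the first `n_nodes - 2 * n_extra` nodes (which must be
#'   >= 2), the planted matching among the rest.
#' @param strength_extra Strength of the patient-only edges.
#' @param n_per_group Subjects per group.
#' @param duration,fs Recording length (s) and sampling rate (Hz).
#' @param seed Integer seed.
#' @return List: `cohort` and `planted` (tibble of the patient-only edges).
#' @export
planted_cohort <- function(n_nodes = 32, n_common = 10, n_extra = 10,
                           strength_extra = 0.6, n_per_group = 20,
                           duration = 140, fs = 600, seed = 1L) {
  n_backbone <- n_nodes - 2L * n_extra
  stopifnot(n_backbone >= 2)
  spec_c <- make_coupling_spec(n_backbone, n_common, seed = seed + 11L)
  spec_c$n_nodes <- as.integer(n_nodes)
  withr_seed(seed + 13L, {
    pool <- n_backbone + sample.int(2L * n_extra) - 1L
    planted <- tibble::tibble(
      source = pool[seq_len(n_extra) * 2L - 1L],
      target = pool[seq_len(n_extra) * 2L],
      strength = rep(strength_extra, n_extra),
      delay = sample(10:30, n_extra, replace = TRUE)
    )
  })
  spec_p <- spec_c
  spec_p$edges <- rbind(spec_c$edges, planted)
  cohort <- simulate_cohort(spec_c, spec_p, n_per_group, duration, fs,
                            seed = seed)
  list(cohort = cohort, planted = planted)
}

#' Planted-difference recovery study (full pipeline)
#'
#' Runs the complete analysis on a [planted_cohort()] and scores how well
#' the FDR-thresholded group-difference network in the hyper-connectivity
#' direction (patients > controls) recovers the planted patient-only edges.
#'
#' @param seed Integer seed.
#' @param n_per_group,n_nodes,n_extra,strength_extra Cohort design.
#' @param duration Per-subject recording seconds.
#' @param n_permutations,fdr_q Test settings.
#' @param bins Histogram bins per axis (default: occupancy-sized).
#' @return List: `precision`, `recall`, `n_detected`, the `report`, and the
#'   planted edge tibble.
#' @export
planted_difference_study <- function(seed = 1L, n_per_group = 20,
                                     n_nodes = 32, n_extra = 10,
                                     strength_extra = 0.6, duration = 140,
                                     n_permutations = 2000, fdr_q = 0.001,
                                     bins = NULL) {
  cfg <- pipeline_config(n_permutations = n_permutations, fdr_q = fdr_q,
                         seed = seed)
  if (is.null(bins)) {
    bins <- choose_bin_count(round(cfg$epoch_seconds * cfg$fs), "occupancy")
  }
  cfg$bins <- bins
  pc <- planted_cohort(n_nodes = n_nodes, n_extra = n_extra,
                       strength_extra = strength_extra,
                       n_per_group = n_per_group, duration = duration,
                       fs = cfg$fs, seed = seed)
  report <- run_pipeline(cfg, cohort = pc$cohort, verbose = FALSE)
  hyper <- extract_significant_network(report$stats$difference,
                                       report$masks$difference,
                                       alpha_q = fdr_q,
                                       direction = "positive")
  got <- paste(hyper$edges$source, hyper$edges$target)
  truth <- paste(pc$planted$source, pc$planted$target)
  list(
    precision = if (length(got)) mean(got %in% truth) else NA_real_,
    recall = mean(truth %in% got),
    n_detected = length(got),
    report = report,
    planted = pc$planted
  )
}

#' Null-calibration study for the edge-wise permutation tests
#'
#' Connectome stacks of i.i.d. standard-normal edge weights carry no signal;
#' both tests' p-values should then be uniform, so the fraction of p < alpha
#' should sit inside the binomial band around alpha, and FDR at small q
#' should reject (essentially) nothing.
#'
#' @param seed Integer seed.
#' @param n_subjects Subjects per group.
#' @param n_nodes Node count (32 gives 992 directed edges).
#' @param n_permutations Permutations per test.
#' @param alpha Nominal level for the rejection-rate check.
#' @param fdr_q FDR level for the false-edge count.
#' @return One-row tibble: rejection rates and FDR edge counts for the
#'   one-sample (sign-flip) and two-sample (label-permutation) tests, the
#'   edge count, and the binomial band.
#' @export
null_calibration_study <- function(seed = 1L, n_subjects = 20, n_nodes = 32,
                                   n_permutations = 1000, alpha = 0.05,
                                   fdr_q = 0.001) {
  make_null <- function(s) {
    withr_seed(s, {
      lapply(seq_len(n_subjects), function(i) {
        w <- matrix(rnorm(n_nodes^2), n_nodes, n_nodes)
        diag(w) <- 0
        connectome(w, "zscore")
      })
    })
  }
  base <- as.integer(seed) %% 100000000L
  ca <- make_null(base * 13L + 1L)
  cb <- make_null(base * 13L + 2L)
  st1 <- edgewise_one_sample_test(ca, n_permutations, seed = seed + 3L)
  st2 <- edgewise_two_sample_test(ca, cb, n_permutations, seed = seed + 4L)
  m <- n_nodes * (n_nodes - 1)
  half_band <- 1.96 * sqrt(alpha * (1 - alpha) / m)
  tibble::tibble(
    rate_one_sample = mean(st1$p < alpha, na.rm = TRUE),
    rate_two_sample = mean(st2$p < alpha, na.rm = TRUE),
    fdr_edges_one_sample = sum(fdr_threshold(st1$p, fdr_q)),
    fdr_edges_two_sample = sum(fdr_threshold(st2$p, fdr_q)),
    n_edges = m,
    band_lo = alpha - half_band,
    band_hi = alpha + half_band
  )
}

#' Surrogate negative-control study (full pipeline)
#'
#' Runs the complete analysis on a planted cohort whose epochs are replaced
#' by phase-randomized surrogates (amplitude spectra preserved, cross-channel
#' phase coupling destroyed). With no coupling left, the group-difference
#' network should be empty even at a permissive FDR level.
#'
#' @param seed Integer seed.
#' @param fdr_q Permissive FDR level (default 0.1).
#' @param n_per_group,duration,n_permutations As in
#'   [planted_difference_study()].
#' @return List: `n_significant_edges` (group difference at `fdr_q`) and the
#'   `report`.
#' @export
surrogate_control_study <- function(seed = 1L, fdr_q = 0.1, n_per_group = 10,
                                    duration = 140, n_permutations = 2000) {
  cfg <- pipeline_config(n_permutations = n_permutations, fdr_q = fdr_q,
                         seed = seed, surrogate_control = TRUE)
  cfg$bins <- choose_bin_count(round(cfg$epoch_seconds * cfg$fs), "occupancy")
  pc <- planted_cohort(n_per_group = n_per_group, duration = duration,
                       fs = cfg$fs, seed = seed)
  report <- run_pipeline(cfg, cohort = pc$cohort, verbose = FALSE)
  list(n_significant_edges = nrow(report$network_difference$edges),
       report = report)
}
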