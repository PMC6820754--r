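#' Define a planted set of directed delayed couplings
#'
#' A coupling spec is the ground truth of a simulated cohort: a directed,
#' weighted edge set over `n_nodes` abstract sources, each edge carrying a
#' coupling strength in `[0, 1)` and a transmission delay in samples, plus
#' the passband and noise level of the intrinsic node signals.
#'
#' @param n_nodes Number of nodes (sources) in the simulated source space.
#' @param n_edges Number of distinct directed edges to plant (no self-loops).
#' @param strength_range Length-2 numeric, coupling strengths drawn uniformly
#'   from this interval; must lie within `[0, 1)`.
#' @param delay_range Length-2 integer, per-edge delays in samples (>= 1).
#' @param seed Integer seed; the same seed reproduces the same edge set.
#' @param base_band Length-2 numeric (Hz), passband of the intrinsic
#'   band-limited noise of every node.
#' @param noise_sd Standard deviation of the intrinsic noise before
#'   renormalization.
#'
#' @return An object of class `coupling_spec`: a list with `n_nodes`, a
#'   tibble `edges` (`source`, `target`, `strength`, `delay`), `base_band`
#'   and `noise_sd`.
#' @examples
#' spec <- make_coupling_spec(20, 15, seed = 1)
#' spec$edges
#' @export
make_coupling_spec <- function(n_nodes, n_edges,
                               strength_range = c(0.4, 0.8),
                               delay_range = c(10, 30),
                               seed = 1L,
                               base_band = c(0.5, 35),
                               noise_sd = 1) {
  stopifnot(n_nodes >= 2, is.finite(n_edges))
  max_edges <- n_nodes * (n_nodes - 1)
  if (n_edges < 1 || n_edges > max_edges) {
    stop("n_edges must be in [1, ", max_edges, "] for ", n_nodes,
         " nodes (no self-loops); got ", n_edges)
  }
  stopifnot(length(strength_range) == 2, all(strength_range >= 0),
            all(strength_range < 1),
            length(delay_range) == 2, all(delay_range >= 1))
  withr_seed(seed, {
    # sample ordered pairs without replacement, excluding the diagonal
    pair_ids <- sample.int(max_edges, n_edges)
    src <- (pair_ids - 1L) %/% (n_nodes - 1L)
    off <- (pair_ids - 1L) %% (n_nodes - 1L)
    tgt <- ifelse(off >= src, off + 1L, off)
    strength <- runif(n_edges, strength_range[1], strength_range[2])
    delay <- if (delay_range[1] == delay_range[2]) {
      rep(as.integer(delay_range[1]), n_edges)
    } else {
      sample(seq.int(delay_range[1], delay_range[2]), n_edges, replace = TRUE)
    }
  })
  spec <- list(
    n_nodes = as.integer(n_nodes),
    edges = tibble::tibble(source = as.integer(src), target = as.integer(tgt),
                           strength = strength, delay = as.integer(delay)),
    base_band = base_band,
    noise_sd = noise_sd
  )
  class(spec) <- "coupling_spec"
  validate_coupling_spec(spec)
}

validate_coupling_spec <- function(spec) {
  e <- spec$edges
  stopifnot(
    all(e$source != e$target),
    all(e$source >= 0), all(e$target >= 0),
    all(e$source < spec$n_nodes), all(e$target < spec$n_nodes),
    all(e$delay >= 1), all(e$strength >= 0), all(e$strength < 1),
    !anyDuplicated(e[c("source", "target")]),
    all(is.finite(spec$base_band)), spec$noise_sd > 0
  )
  spec
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat("<coupling_spec> ", x$n_nodes, " nodes, ", nrow(x$edges),
      " directed edges, band ", x$base_band[1], "-", x$base_band[2],
      " Hz\n", sep = "")
  print(x$edges, n = 5)
  invisible(x)
}

# run code under a fixed seed without disturbing the caller's RNG stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

# band-limited Gaussian noise via spectral masking: white noise, FFT, zero
# the out-of-band coefficients, inverse FFT. Exactly band-limited and
# variance-normalized.
band_limited_noise <- function(n, fs, band, sd = 1) {
  x <- rnorm(n)
  f <- fft_freqs(n, fs)
  keep <- abs(f) >= band[1] & abs(f) <= band[2]
  X <- fft(x)
  X[!keep] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) stop("band contains no Fourier frequencies at this length/fs")
  y * (sd / s)
}

fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

#' Simulate one subject's source-space recording
#'
#' Each node is intrinsic band-limited Gaussian noise; each planted edge adds
#' `strength` times the source node's intrinsic signal, delayed by the edge's
#' delay, into the target. Rows are renormalized to unit variance so strength
#' is interpretable as relative drive.
#'
#' @param spec A [make_coupling_spec()] object.
#' @param duration Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param subject_id Optional subject identifier stored on the result.
#' @return A `source_ts` object: list with `data` (`n_nodes` x samples
#'   matrix), `fs` and `subject_id`.
#' @examples
#' spec <- make_coupling_spec(5, 4, seed = 2)
#' ts <- simulate_subject(spec, duration = 8, fs = 600, seed = 1)
#' dim(ts$data)
#' @export
simulate_subject <- function(spec, duration, fs, seed, subject_id = "s1") {
  stopifnot(inherits(spec, "coupling_spec"), is.finite(duration),
            is.finite(fs), fs > 0)
  n <- round(duration * fs)
  max_delay <- if (nrow(spec$edges)) max(spec$edges$delay) else 0L
  if (n < max_delay + 2) {
    stop("duration * fs = ", n, " samples but max delay + 2 = ",
         max_delay + 2, " are required")
  }
  # generate at a 2-3-5-smooth length so the FFT stays O(n log n), then slice
  n_pad <- stats::nextn(n + max_delay, c(2, 3, 5))
  withr_seed(seed, {
    base <- matrix(0, spec$n_nodes, n_pad)
    for (i in seq_len(spec$n_nodes)) {
      base[i, ] <- band_limited_noise(n_pad, fs, spec$base_band,
                                      sd = spec$noise_sd)
    }
  })
  out <- base[, (max_delay + 1):(max_delay + n), drop = FALSE]
  if (nrow(spec$edges)) {
    for (k in seq_len(nrow(spec$edges))) {
      e <- spec$edges[k, ]
      idx <- (max_delay + 1 - e$delay):(max_delay + n - e$delay)
      out[e$target + 1L, ] <- out[e$target + 1L, ] +
        e$strength * base[e$source + 1L, idx]
    }
  }
  out <- out / apply(out, 1, sd)
  structure(list(data = out, fs = fs, subject_id = subject_id),
            class = "source_ts")
}

#' @export
print.source_ts <- function(x, ...) {
  cat("<source_ts> subject ", x$subject_id, ": ", nrow(x$data), " nodes x ",
      ncol(x$data), " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Simulate a two-group cohort with known coupling differences
#'
#' Generates `n_per_group` patients and controls from two coupling specs
#' sharing a node set. Per-subject seeds are derived deterministically from
#' the master seed, so the same seed reproduces the cohort bit for bit.
#' Behavioral scores are drawn on their instrument scales (THI and VAS on
#' 0-100, hearing loss in dB HL); [simulate_behavioral_scores()] can replace
#' any column with scores calibrated against a network metric.
#'
#' @param spec_control,spec_patient Coupling specs for the two groups; must
#'   share `n_nodes`.
#' @param n_per_group Subjects per group.
#' @param duration,fs Passed to [simulate_subject()].
#' @param seed Master integer seed.
#' @return A `cohort` object: list with `series` (list of `source_ts`) and
#'   `subjects`, a tibble with `subject`, `group` and behavioral score
#'   columns (`THI`, `VAS_loudness`, `VAS_distress`, `VAS_handicap`,
#'   `hearing_loss`).
#' @export
simulate_cohort <- function(spec_control, spec_patient, n_per_group,
                            duration, fs, seed) {
  stopifnot(inherits(spec_control, "coupling_spec"),
            inherits(spec_patient, "coupling_spec"))
  if (spec_control$n_nodes != spec_patient$n_nodes) {
    stop("control and patient specs must share n_nodes (",
         spec_control$n_nodes, " vs ", spec_patient$n_nodes, ")")
  }
  n_total <- 2L * n_per_group
  group <- rep(c("control", "patient"), each = n_per_group)
  ids <- sprintf("%s%02d", ifelse(group == "control", "c", "p"),
                 c(seq_len(n_per_group), seq_len(n_per_group)))
  subject_seeds <- (as.integer(seed) %% 100000L) * 10000L + seq_len(n_total)
  series <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sp <- if (group[i] == "control") spec_control else spec_patient
    series[[i]] <- simulate_subject(sp, duration, fs, seed = subject_seeds[i],
                                    subject_id = ids[i])
  }
  withr_seed(as.integer(seed) + 777L, {
    clip01 <- function(x) pmin(100, pmax(0, x))
    subjects <- tibble::tibble(
      subject = ids,
      group = group,
      THI = clip01(round(rnorm(n_total, 24, 11))),
      VAS_loudness = clip01(round(rnorm(n_total, 42, 26))),
      VAS_distress = clip01(round(rnorm(n_total, 24, 11))),
      VAS_handicap = clip01(round(rnorm(n_total, 31, 24))),
      hearing_loss = pmax(0, round(rnorm(n_total, 15, 8)))
    )
    subjects[subjects$group == "control",
             c("THI", "VAS_loudness", "VAS_distress", "VAS_handicap")] <- 0
  })
  structure(list(series = series, subjects = subjects,
                 spec_control = spec_control, spec_patient = spec_patient,
                 fs = fs, seed = as.integer(seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", length(x$series), " subjects (",
      sum(x$subjects$group == "patient"), " patients, ",
      sum(x$subjects$group == "control"), " controls), ",
      x$spec_control$n_nodes, " nodes @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Generate behavioral scores with a target correlation to a metric
#'
#' Builds scores as a linear transform of the standardized metric plus
#' Gaussian noise whose variance is calibrated in closed form so the
#' population correlation equals `target_r`, then maps the result into
#' `score_range` (centered, SD = width/6) and clips.
#'
#' @param metric_per_subject Numeric vector of a per-subject network metric.
#' @param target_r Desired population Pearson correlation, in `[-1, 1]`.
#' @param score_range Length-2 numeric, the instrument scale (e.g. `c(0, 100)`).
#' @param seed Integer seed.
#' @return Numeric vector of scores, same length as the input.
#' @examples
#' m <- rnorm(40)
#' s <- simulate_behavioral_scores(m, target_r = -0.6, c(0, 100), seed = 3)
#' cor(m, s)
#' @export
simulate_behavioral_scores <- function(metric_per_subject, target_r,
                                       score_range = c(0, 100), seed = 1L) {
  n <- length(metric_per_subject)
  stopifnot(n >= 3, abs(target_r) <= 1, length(score_range) == 2,
            score_range[2] > score_range[1])
  if (sd(metric_per_subject) == 0) {
    stop("metric vector is constant; correlation with it is undefined")
  }
  z <- as.numeric(scale(metric_per_subject))
  withr_seed(seed, eps <- rnorm(n))
  latent <- target_r * z + sqrt(1 - target_r^2) * eps
  mid <- mean(score_range)
  width <- diff(score_range)
  pmin(score_range[2], pmax(score_range[1], mid + latent * width / 6))
}
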