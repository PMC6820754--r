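#' Band-limit a recording the way resting-state pipelines do
#'
#' Applies, in order: a causal (forward-only) Butterworth high-pass, a
#' forward-only notch at the mains frequency, and a zero-phase
#' (forward-backward) Butterworth low-pass. All three run on the continuous
#' recording, before epoching.
#'
#' @param series A `source_ts` object (see [simulate_subject()]).
#' @param highpass_hz High-pass corner (Hz); forward Butterworth.
#' @param notch_hz Mains notch center (Hz); set `NULL` to skip.
#' @param lowpass_hz Low-pass corner (Hz); zero-phase Butterworth.
#' @param order Butterworth order for both high- and low-pass.
#' @param notch_q Quality factor of the second-order notch (bandwidth =
#'   `notch_hz / notch_q`).
#' @return A filtered `source_ts` of the same shape.
#' @export
apply_filters <- function(series, highpass_hz = 0.5, notch_hz = 50,
                          lowpass_hz = 35, order = 4, notch_q = 30) {
  stopifnot(inherits(series, "source_ts"))
  fs <- series$fs
  nyq <- fs / 2
  if (!(highpass_hz > 0 && highpass_hz < lowpass_hz && lowpass_hz < nyq)) {
    stop("need 0 < highpass (", highpass_hz, ") < lowpass (", lowpass_hz,
         ") < fs/2 (", nyq, ")")
  }
  if (!is.null(notch_hz) && notch_hz >= nyq) {
    stop("notch frequency ", notch_hz, " Hz is at or above Nyquist ", nyq)
  }
  hp <- signal::butter(order, highpass_hz / nyq, type = "high")
  lp <- signal::butter(order, lowpass_hz / nyq, type = "low")
  nf <- if (!is.null(notch_hz)) notch_biquad(notch_hz, fs, notch_q)
  x <- series$data
  for (i in seq_len(nrow(x))) {
    v <- signal::filter(hp, x[i, ])                   # causal high-pass
    if (!is.null(nf)) v <- signal::filter(nf, v)      # causal notch
    v <- signal::filtfilt(lp, as.numeric(v))          # zero-phase low-pass
    x[i, ] <- as.numeric(v)
  }
  series$data <- x
  series
}

# RBJ-cookbook second-order IIR notch (unit gain away from the notch).
notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Draw non-overlapping epochs pseudo-randomly from a recording
#'
#' Picks `n_epochs` starts uniformly at random from the recording after
#' discarding the first `exclude_seconds`, rejecting draws until the epochs
#' are pairwise non-overlapping. If rejection sampling stalls on a tightly
#' packed recording, a seeded jittered partition is used instead.
#'
#' @param series A `source_ts` object.
#' @param n_epochs Number of epochs.
#' @param epoch_seconds Epoch length in seconds.
#' @param exclude_seconds Initial stretch of the recording never sampled.
#' @param seed Integer seed; fixed seed gives identical `epoch_starts`.
#' @return An `epoch_set`: list with `epochs` (list of node x sample
#'   matrices), `fs` and `epoch_starts` (1-based sample indices into the
#'   parent recording).
#' @export
segment_epochs <- function(series, n_epochs = 8, epoch_seconds = 8,
                           exclude_seconds = 60, seed = 1L) {
  stopifnot(inherits(series, "source_ts"), n_epochs >= 1)
  fs <- series$fs
  n <- ncol(series$data)
  len <- round(epoch_seconds * fs)
  first <- round(exclude_seconds * fs) + 1L
  avail <- n - first + 1L
  need <- n_epochs * len
  if (avail < need) {
    stop("recording offers ", avail, " usable samples after excluding ",
         exclude_seconds, " s but ", n_epochs, " epochs of ", epoch_seconds,
         " s need ", need, " (short by ", need - avail, ")")
  }
  starts <- NULL
  withr_seed(seed, {
    for (try in seq_len(1000L)) {
      cand <- sort(sample.int(n - first - len + 2L, n_epochs) + first - 1L)
      if (n_epochs == 1 || all(diff(cand) >= len)) {
        starts <- cand
        break
      }
    }
    if (is.null(starts)) {
      # tight fit: partition the usable range into n_epochs slots and
      # jitter each epoch inside its slot
      slack <- avail - need
      gaps <- if (slack > 0) {
        tabulate(sample.int(n_epochs + 1L, slack, replace = TRUE),
                 n_epochs + 1L)
      } else rep(0L, n_epochs + 1L)
      starts <- first + cumsum(c(0L, rep(len, n_epochs - 1L))) +
        cumsum(gaps[seq_len(n_epochs)])
    }
  })
  epochs <- lapply(starts, function(s) {
    series$data[, s:(s + len - 1L), drop = FALSE]
  })
  structure(list(epochs = epochs, fs = fs,
                 epoch_starts = as.integer(starts)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", length(x$epochs), " epochs of ",
      ncol(x$epochs[[1]]), " samples (", nrow(x$epochs[[1]]),
      " nodes) @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}
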