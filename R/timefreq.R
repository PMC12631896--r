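#' Short-time Fourier transform specification
#'
#' @param window_length Window length N in samples.
#' @param hop Hop (frame step) in samples; default 50% overlap.
#' @param fs Sampling rate, Hz.
#' @param window Window function taking N and returning N weights
#'   (default Hann).
#' @return An object of class `stft_spec`.
#' @export
stft_spec <- function(window_length, hop = max(1L, window_length %/% 2L), fs,
                      window = hann_window) {
  window_length <- as.integer(window_length)
  hop <- as.integer(hop)
  if (hop < 1 || hop > window_length)
    stopf("hop must satisfy 0 < hop <= window length")
  structure(list(window_length = window_length, hop = hop, fs = fs,
                 window = window), class = "stft_spec")
}

#' @rdname stft_spec
#' @param n Window length.
#' @export
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' @rdname stft_spec
#' @export
rect_window <- function(n) rep(1, n)

#' Spectrogram: STFT power on a time-frequency grid
#'
#' Computes one-sided magnitude-squared short-time Fourier coefficients.
#' Power is normalized so that with a rectangular window and hop = N the sum
#' over all bins and frames equals the total signal energy (Parseval):
#' non-DC/non-Nyquist bins carry a factor 2 for the folded negative
#' frequencies.
#'
#' @param signal Finite numeric vector.
#' @param spec An [stft_spec()].
#' @return An object of class `spectrogram` with fields `power`
#'   (freq bins x frames, non-negative), `freqs` (Hz) and `times` (s, window
#'   centers).
#' @export
stft <- function(signal, spec) {
  if (!all(is.finite(signal))) stopf("signal contains non-finite values")
  N <- spec$window_length
  if (length(signal) < N)
    stopf("signal length %d is shorter than the %d-sample window",
          length(signal), N)
  w <- spec$window(N)
  starts <- seq(1, length(signal) - N + 1, by = spec$hop)
  half <- N %/% 2
  nb <- half + 1
  scale <- c(1, rep(2, nb - 2), if (N %% 2 == 0) 1 else 2)[seq_len(nb)]
  pow <- vapply(starts, function(s) {
    X <- stats::fft(signal[s:(s + N - 1)] * w)[seq_len(nb)]
    scale * (Mod(X)^2) / N
  }, numeric(nb))
  pow <- matrix(pow, nrow = nb)
  structure(list(power = pow,
                 freqs = (seq_len(nb) - 1) * spec$fs / N,
                 times = (starts - 1 + (N - 1) / 2) / spec$fs),
            class = "spectrogram")
}

#' Band-limited power trace of a spectrogram
#'
#' Sums spectrogram power over all frequency bins within a band (inclusive
#' bounds), producing one value per time frame. Used to profile the canonical
#' EEG bands (delta, theta, alpha 8-12 Hz, beta 12-27 Hz, gamma) and the
#' event-related desynchronization they show during motor imagery.
#'
#' @param spec A `spectrogram`.
#' @param band `(low, high)` in Hz.
#' @return Numeric vector of per-frame band power.
#' @export
band_energy <- function(spec, band) {
  keep <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (!any(keep))
    stopf("band (%g, %g) Hz contains no frequency bins", band[1], band[2])
  colSums(spec$power[keep, , drop = FALSE])
}

#' Canonical EEG frequency bands (Hz)
#'
#' Alpha and beta follow the motor-imagery convention (8-12, 12-27 Hz);
#' delta/theta/gamma take conventional edges.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 27), gamma = c(27, 45))
}

#' Trial-averaged spectrogram of one channel
#'
#' Elementwise mean of the per-trial spectrograms of a channel, the estimate
#' used to visualize event-related desynchronization across repeated trials.
#'
#' @param ts A [trial_set()].
#' @param channel Channel name or index.
#' @param spec An [stft_spec()].
#' @param trials Optional trial indices (default all).
#' @return A `spectrogram`.
#' @export
trial_averaged_spectrogram <- function(ts, channel, spec,
                                       trials = seq_len(dim(ts$data)[1])) {
  if (is.character(channel)) {
    idx <- match(channel, ts$channel_names)
    if (is.na(idx)) stopf("channel '%s' not found", channel)
  } else idx <- channel
  if (is.na(idx) || idx < 1 || idx > dim(ts$data)[2])
    stopf("channel index %s out of range", as.character(channel))
  if (!length(trials)) stopf("need at least one trial")
  acc <- NULL
  for (i in trials) {
    sg <- stft(ts$data[i, idx, ], spec)
    acc <- if (is.null(acc)) sg else {
      sg$power <- sg$power + acc$power; sg
    }
  }
  acc$power <- acc$power / length(trials)
  acc
}

#' Task / baseline band-power ratio
#'
#' Mean band power over task-window samples divided by mean band power over a
#' baseline segment of the same channel; the event-related desynchronization
#' statistic. For an oscillation whose amplitude drops by a factor
#' `(1 - depth)` during the task, the expected ratio is `(1 - depth)^2`.
#'
#' @param task Numeric vector (task-window signal).
#' @param baseline Numeric vector (baseline signal).
#' @param fs Sampling rate, Hz.
#' @param band Frequency band `(low, high)` Hz.
#' @param window_s STFT window length in seconds (default 1).
#' @return Scalar power ratio.
#' @export
band_power_ratio <- function(task, baseline, fs, band = c(8, 12),
                             window_s = 1) {
  sp <- stft_spec(round(window_s * fs), fs = fs)
  mean(band_energy(stft(task, sp), band)) /
    mean(band_energy(stft(baseline, sp), band))
}
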