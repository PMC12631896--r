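#' Continuous multichannel recording
#'
#' A raw continuous recording of one modality for one subject: a
#' `channels x samples` matrix with per-trial event markers (sample index of
#' cue onset plus class label). fNIRS recordings in optical density carry the
#' two laser wavelengths and the source-detector separation; channels are
#' wavelength-blocked (all optode pairs at the first wavelength, then all at
#' the second).
#'
#' @param data Numeric matrix `channels x samples`.
#' @param fs Sampling rate, Hz.
#' @param events Data frame with columns `sample` (1-based cue-onset index,
#'   strictly increasing) and `label` (class name).
#' @param channel_names Optional channel names.
#' @param wavelengths fNIRS laser wavelengths in nm (length 2), or `NULL`.
#' @param source_detector_distance Optode separation in cm (default 3).
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, fs, events, channel_names = NULL,
                                 wavelengths = NULL,
                                 source_detector_distance = 3) {
  if (!is.matrix(data)) stopf("data must be a channels x samples matrix")
  if (fs <= 0) stopf("fs must be > 0")
  ev <- as.data.frame(events)
  if (!all(c("sample", "label") %in% names(ev)))
    stopf("events needs columns 'sample' and 'label'")
  if (any(diff(ev$sample) <= 0))
    stopf("event sample indices must be strictly increasing")
  if (any(ev$sample < 1 | ev$sample > ncol(data)))
    stopf("event at sample %d lies outside the %d-sample record",
          ev$sample[which(ev$sample < 1 | ev$sample > ncol(data))[1]],
          ncol(data))
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  structure(list(data = data, fs = fs, events = ev,
                 channel_names = as.character(channel_names),
                 wavelengths = wavelengths,
                 source_detector_distance = source_detector_distance),
            class = "continuous_recording")
}

# Zero-phase band-pass by FFT-domain multiplication with a real, raised-cosine
# edged frequency response. Exactly linear and phase-free; the record is
# reflection-padded to suppress circular wrap-around at the edges.
bandpass_fft <- function(x, fs, low, high, transition = NULL) {
  n <- length(x)
  if (is.null(transition))
    transition <- c(max(low, 1e-6), max(min(high * 0.2, (fs / 2 - high)), fs / n))
  p <- min(n - 1, ceiling(3 * fs / max(low, fs / n)))
  xp <- c(rev(x[seq(2, p + 1)]), x, rev(x[seq(n - p, n - 1)]))
  np <- length(xp)
  f <- (seq_len(np) - 1) / np * fs
  f <- pmin(f, fs - f)  # fold two-sided grid onto [0, fs/2]
  H <- rep(1, np)
  lo_a <- max(0, low - transition[1] / 2); lo_b <- low + transition[1] / 2
  hi_a <- high - transition[2] / 2; hi_b <- min(fs / 2, high + transition[2] / 2)
  if (low > 0) {
    H[f <= lo_a] <- 0
    ramp <- f > lo_a & f < lo_b
    H[ramp] <- 0.5 - 0.5 * cos(pi * (f[ramp] - lo_a) / (lo_b - lo_a))
  }
  H[f >= hi_b] <- 0
  ramp <- f > hi_a & f < hi_b
  H[ramp] <- 0.5 + 0.5 * cos(pi * (f[ramp] - hi_a) / (hi_b - hi_a))
  y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / np
  y[seq(p + 1, p + n)]
}

# FFT (Fourier-domain) resampling of a real signal to n_out samples, as an
# anti-aliased decimation/interpolation in one step.
resample_fft <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  nmin <- min(n, n_out)
  half <- nmin %/% 2
  idx_pos <- seq_len(half + 1)                      # DC .. +Nyquist(ish)
  Y[idx_pos] <- X[idx_pos]
  if (half > 1) {
    idx_neg_y <- n_out - seq_len(half - 1) + 1
    idx_neg_x <- n - seq_len(half - 1) + 1
    Y[idx_neg_y] <- X[idx_neg_x]
  }
  if (nmin %% 2 == 0) {                             # split shared Nyquist bin
    k <- half + 1
    if (n_out < n) {
      Y[k] <- X[k] + X[n - half + 1]
      Y[k] <- Re(Y[k])
    } else {
      Y[k] <- X[k] / 2
      Y[n_out - half + 1] <- Conj(Y[k])
    }
  }
  # ifft/n_out times the amplitude-preserving factor n_out/n collapses to /n
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# Cut fixed-length epochs from a continuous matrix. Never reads outside the
# record: raises naming the offending event.
epoch_trials <- function(data, event_samples, offset_samples, n_samples) {
  n_rec <- ncol(data)
  out <- array(0, dim = c(length(event_samples), nrow(data), n_samples))
  for (i in seq_along(event_samples)) {
    a <- event_samples[i] + offset_samples
    b <- a + n_samples - 1
    if (a < 1 || b > n_rec)
      stopf("event %d (sample %d) needs samples %d..%d outside the %d-sample record",
            i, event_samples[i], a, b, n_rec)
    out[i, , ] <- data[, a:b, drop = FALSE]
  }
  out
}

labels_from_events <- function(events, classes) {
  lab <- match(as.character(events$label), classes) - 1L
  if (anyNA(lab))
    stopf("event label '%s' not in classes (%s)",
          events$label[which(is.na(lab))[1]], paste(classes, collapse = ", "))
  lab
}

#' Preprocess a raw EEG recording into a trial set
#'
#' Implements the EEG protocol: down-sampling to a common 200 Hz rate
#' (Fourier-domain, anti-aliased), 0.5-50 Hz zero-phase band-pass, epoching
#' over the motor-imagery task window, and per-channel baseline correction by
#' subtracting the mean of a 3 s pre-stimulus (pre-cue) interval. A 10 s task
#' at 200 Hz yields 2000 samples per trial.
#'
#' @param rec A [continuous_recording()] (microvolts). Events mark cue onset.
#' @param paradigm A [paradigm_spec()].
#' @param target_fs Target sampling rate after down-sampling (Hz).
#' @param band Band-pass edges `(low, high)` in Hz.
#' @param baseline_s Pre-stimulus baseline window length (s).
#' @param include_cue If `TRUE` the trial window starts at cue onset instead
#'   of task onset (cue excluded by default).
#' @param subject_id Subject identifier recorded in the output.
#' @return A [trial_set()] at `target_fs`.
#' @export
preprocess_eeg <- function(rec, paradigm, target_fs = 200,
                           band = c(0.5, 50), baseline_s = 3,
                           include_cue = FALSE, subject_id = "subject") {
  if (rec$fs < 2 * band[2])
    stopf("sampling rate %g Hz is below Nyquist for band edge %g Hz",
          rec$fs, band[2])
  if (band[1] < 0 || band[1] >= band[2] || band[2] >= target_fs / 2)
    stopf("invalid band (%g, %g) for target rate %g", band[1], band[2], target_fs)
  ratio <- target_fs / rec$fs
  if (abs(ratio - 1) > 1e-12) {
    n_out <- round(ncol(rec$data) * ratio)
    dat <- t(apply(rec$data, 1, resample_fft, n_out = n_out))
    ev <- round((rec$events$sample - 1) * ratio) + 1
  } else {
    dat <- rec$data
    ev <- rec$events$sample
  }
  dat <- t(apply(dat, 1, bandpass_fft, fs = target_fs,
                 low = band[1], high = band[2]))
  offset <- if (include_cue) 0L else round(paradigm$cue_duration_s * target_fs)
  n_task <- round(paradigm$task_duration_s * target_fs)
  n_base <- round(baseline_s * target_fs)
  trials <- epoch_trials(dat, ev, offset, n_task)
  base <- epoch_trials(dat, ev, -n_base, n_base)
  for (i in seq_len(dim(trials)[1]))
    trials[i, , ] <- trials[i, , ] - rowMeans(base[i, , , drop = FALSE][1, , , drop = TRUE])
  trial_set(subject_id, "EEG", trials,
            labels_from_events(rec$events, paradigm$classes),
            target_fs, rec$channel_names, paradigm$classes)
}

# Default extinction coefficients (cm^-1 per mM) for oxy/deoxy-hemoglobin at
# the common fNIRS laser lines.
default_extinction_table <- function() {
  data.frame(wavelength = c(690, 760, 780, 808, 830, 850),
             eps_hbo = c(0.2764, 0.5864, 0.7360, 0.8434, 0.9741, 1.0580),
             eps_hbr = c(2.0518, 1.5486, 1.3514, 0.8122, 0.6931, 0.6913))
}

#' Modified Beer-Lambert conversion of optical density to hemodynamics
#'
#' Solves, per optode pair and time point, the 2x2 linear system
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * d * DPF(lambda)`
#' for the oxygenated and deoxygenated hemoglobin concentration changes.
#' Input channels must be wavelength-blocked; the output doubles the pair
#' count into an HbO block followed by an HbR block.
#'
#' @param rec [continuous_recording()] of optical density with two wavelengths.
#' @param extinction_table Data frame `wavelength`, `eps_hbo`, `eps_hbr`
#'   (cm^-1 per mM); defaults to literature values.
#' @param dpf Differential pathlength factors, one per wavelength.
#' @return A [continuous_recording()] whose channels are `dHbO` then `dHbR`
#'   per optode pair (mM).
#' @export
beer_lambert <- function(rec, extinction_table = default_extinction_table(),
                         dpf = c(6, 6)) {
  wl <- rec$wavelengths
  if (is.null(wl) || length(wl) != 2)
    stopf("recording must carry exactly two wavelengths, got %s",
          paste(wl, collapse = ", "))
  if (nrow(rec$data) %% 2 != 0)
    stopf("optical-density channel count must be even (wavelength-blocked)")
  eps <- t(vapply(wl, function(w) {
    i <- which(abs(extinction_table$wavelength - w) <= 5)
    if (!length(i)) stopf("no extinction coefficients for wavelength %g nm", w)
    i <- i[which.min(abs(extinction_table$wavelength[i] - w))]
    c(extinction_table$eps_hbo[i], extinction_table$eps_hbr[i])
  }, numeric(2)))
  E <- eps * (rec$source_detector_distance * dpf)  # row i scaled by d*DPF(lambda_i)
  if (abs(det(E)) < 1e-12 * max(abs(E))^2)
    stopf("extinction matrix is singular; wavelengths too close")
  Einv <- solve(E)
  P <- nrow(rec$data) / 2
  od1 <- rec$data[seq_len(P), , drop = FALSE]
  od2 <- rec$data[P + seq_len(P), , drop = FALSE]
  hbo <- Einv[1, 1] * od1 + Einv[1, 2] * od2
  hbr <- Einv[2, 1] * od1 + Einv[2, 2] * od2
  base <- sub("@.*$", "", rec$channel_names[seq_len(P)])
  continuous_recording(rbind(hbo, hbr), rec$fs, rec$events,
                       c(paste0(base, ":HbO"), paste0(base, ":HbR")),
                       wavelengths = NULL,
                       source_detector_distance = rec$source_detector_distance)
}

#' Preprocess an fNIRS concentration recording into a trial set
#'
#' Band-passes the slow hemodynamic band (0.01-0.1 Hz, zero-phase), cuts the
#' task window, and subtracts the mean of a 3 s pre-task interval per channel.
#' Run [beer_lambert()] first if the recording is still optical density.
#'
#' @param rec A [continuous_recording()] in concentration units.
#' @param paradigm A [paradigm_spec()].
#' @param band Band-pass edges in Hz.
#' @param baseline_s Pre-task baseline window (s).
#' @param resample_to Optional per-trial sample count; trials are FFT-resampled
#'   to exactly this length (e.g. 100 to match the printed network input).
#' @param include_cue Start trials at cue onset instead of task onset.
#' @param subject_id Subject identifier for the output.
#' @return A [trial_set()].
#' @export
preprocess_fnirs <- function(rec, paradigm, band = c(0.01, 0.1),
                             baseline_s = 3, resample_to = NULL,
                             include_cue = FALSE, subject_id = "subject") {
  if (!is.null(rec$wavelengths))
    stopf("recording still carries wavelengths; run beer_lambert() first")
  n_base <- round(baseline_s * rec$fs)
  if (rec$events$sample[1] - n_base < 1)
    stopf("record too short: first event at sample %d leaves no %g-s baseline",
          rec$events$sample[1], baseline_s)
  dat <- t(apply(rec$data, 1, bandpass_fft, fs = rec$fs,
                 low = band[1], high = band[2]))
  offset <- if (include_cue) 0L else round(paradigm$cue_duration_s * rec$fs)
  n_task <- floor(paradigm$task_duration_s * rec$fs)
  trials <- epoch_trials(dat, rec$events$sample, offset, n_task)
  base <- epoch_trials(dat, rec$events$sample, -n_base, n_base)
  for (i in seq_len(dim(trials)[1]))
    trials[i, , ] <- trials[i, , ] - rowMeans(base[i, , , drop = FALSE][1, , , drop = TRUE])
  fs_out <- rec$fs
  if (!is.null(resample_to) && resample_to != n_task) {
    res <- array(0, dim = c(dim(trials)[1], dim(trials)[2], resample_to))
    for (i in seq_len(dim(trials)[1]))
      for (ch in seq_len(dim(trials)[2]))
        res[i, ch, ] <- resample_fft(trials[i, ch, ], resample_to)
    trials <- res
    fs_out <- resample_to / paradigm$task_duration_s
  }
  trial_set(subject_id, "FNIRS", trials,
            labels_from_events(rec$events, paradigm$classes),
            fs_out, rec$channel_names, paradigm$classes)
}
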