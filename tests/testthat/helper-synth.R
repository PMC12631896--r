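# Shared fixtures: all test data is generated in code, nothing on disk.

# Fast paradigm / subject factories for tests that do not depend on the
# canonical recording geometry.
tiny_paradigm <- function(task_s = 10)
  paradigm_spec(task_duration_s = task_s, trials_per_class_per_session = 15,
                n_sessions = 2)

tiny_subject <- function(seed = 1L, erd_depth = 0.8, snr = 0.3,
                         n_ch = 8, fs_eeg = 32, laterality = "normal",
                         hemo_gain = 1) {
  generate_subject(subject_profile(erd_depth = erd_depth, snr = snr,
                                   hemo_gain = hemo_gain,
                                   laterality = laterality),
                   tiny_paradigm(), n_channels_eeg = n_ch,
                   n_channels_fnirs = n_ch, fs_eeg = fs_eeg, fs_fnirs = 10,
                   subject_id = sprintf("T%02d", seed), seed = seed)
}

tiny_eeg_spec <- function(n_ch = 8, n_samp = 320)
  scaled_network_spec(n_ch, n_samp)

# Exhaustive minimum-cost matching oracle for W1 between equal-size sample
# sets (enumerates all permutations; n <= 5).
w1_matching_oracle <- function(p, q) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  min(vapply(perms(q), function(qq) mean(abs(p - qq)), numeric(1)))
}

# Central finite-difference gradient of a scalar function of a matrix.
fd_grad <- function(fn, X, h = 1e-5, idx = seq_along(X)) {
  g <- numeric(length(idx))
  for (j in seq_along(idx)) {
    Xp <- X; Xp[idx[j]] <- X[idx[j]] + h
    Xm <- X; Xm[idx[j]] <- X[idx[j]] - h
    g[j] <- (fn(Xp) - fn(Xm)) / (2 * h)
  }
  g
}

rel_err <- function(a, b) abs(a - b) / pmax(1e-7, abs(a) + abs(b))

# Continuous sinusoidal recording with evenly spaced cue events.
sine_recording <- function(freqs, amps, fs, n_trials = 4, paradigm = tiny_paradigm(),
                           n_ch = 2, extra_noise = 0) {
  trial_len <- (3 + paradigm$cue_duration_s + paradigm$task_duration_s + 2) * fs
  n <- n_trials * trial_len + 4 * fs
  t <- (seq_len(n) - 1) / fs
  sig <- rowSums(vapply(seq_along(freqs),
                        function(i) amps[i] * sin(2 * pi * freqs[i] * t),
                        numeric(n)))
  dat <- matrix(sig, n_ch, n, byrow = TRUE)
  if (extra_noise > 0) dat <- dat + extra_noise * matrix(rnorm(n_ch * n), n_ch)
  ev <- data.frame(sample = 4 * fs + (seq_len(n_trials) - 1) * trial_len,
                   label = rep(paradigm$classes, length.out = n_trials))
  continuous_recording(dat, fs, ev)
}
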