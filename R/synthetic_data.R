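# Synthetic hybrid EEG + fNIRS motor-imagery populations.
#
# The generator plants the statistical structure the decoding framework
# assumes: a contralateral alpha/beta event-related desynchronization (ERD)
# during the imagery window on sensorimotor channels, a task-locked
# double-gamma HbO increase with mirrored HbR decrease, 1/f background EEG
# noise, slow physiological fNIRS oscillations, and inter-subject parameter
# variability, with patient-like subjects showing attenuated ERD on the
# impaired side.

#' Subject generative profile
#'
#' @param erd_depth Fractional alpha/beta amplitude reduction during the task
#'   on contralateral sensorimotor channels, in `[0, 1]`.
#' @param erd_band ERD analysis band in Hz (alpha by default; a beta
#'   oscillation at 20 Hz is planted with half amplitude and the same depth).
#' @param hemo_gain Peak HbO response amplitude (concentration units).
#' @param hemo_delay Hemodynamic onset delay after task onset, seconds.
#' @param snr Background-to-signal amplitude ratio (1/f noise SD relative to
#'   the alpha oscillation amplitude); must be > 0.
#' @param spatial_pattern Optional list with per-channel weight vectors
#'   `left` and `right` (one weight per EEG channel); defaults to Gaussian
#'   bumps over the two hemisphere motor regions.
#' @param laterality `"normal"`, `"left_impaired"` or `"right_impaired"`;
#'   impairment multiplies the ERD depth of the affected hand by
#'   `impair_factor`.
#' @param impair_factor ERD attenuation factor on the impaired side.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(erd_depth = 0.6, erd_band = c(8, 12),
                            hemo_gain = 1, hemo_delay = 2, snr = 0.5,
                            spatial_pattern = NULL,
                            laterality = c("normal", "left_impaired",
                                           "right_impaired"),
                            impair_factor = 0.2) {
  laterality <- match.arg(laterality)
  if (erd_depth < 0 || erd_depth > 1) stopf("erd_depth must lie in [0, 1]")
  if (snr <= 0) stopf("snr must be > 0")
  structure(list(erd_depth = erd_depth, erd_band = erd_band,
                 hemo_gain = hemo_gain, hemo_delay = hemo_delay, snr = snr,
                 spatial_pattern = spatial_pattern, laterality = laterality,
                 impair_factor = impair_factor),
            class = "subject_profile")
}

# Gaussian spatial bumps centred on the two hemisphere motor regions.
# Channels are split left-half / right-half; at least one non-zero weight
# per hemisphere is guaranteed.
default_spatial_pattern <- function(n_channels, jitter = 0) {
  half <- n_channels %/% 2
  centre_l <- (half + 1) / 2 + jitter
  centre_r <- half + (n_channels - half + 1) / 2 + jitter
  idx <- seq_len(n_channels)
  list(left = exp(-((idx - centre_l) / 2)^2) * (idx <= half),
       right = exp(-((idx - centre_r) / 2)^2) * (idx > half))
}

# 1/f-shaped background noise: white Gaussian noise spectrally weighted by
# 1/sqrt(f) (power ~ 1/f) with a 1 Hz flattening floor, scaled to unit SD.
pink_noise <- function(n, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  w <- 1 / sqrt(pmax(f, 1))
  y <- Re(stats::fft(X * w, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' `h(t) = t^5 e^-t / Gamma(6) - ratio * t^15 e^-t / Gamma(16)` (peak ~5 s,
#' undershoot ~15 s), normalized to unit peak.
#'
#' @param t Time in seconds (>= 0 evaluated; negative times give 0).
#' @param ratio Undershoot ratio (default 1/6).
#' @return Kernel values, unit peak.
#' @export
double_gamma_hrf <- function(t, ratio = 1 / 6) {
  h <- ifelse(t > 0,
              t^5 * exp(-t) / gamma(6) - ratio * t^15 * exp(-t) / gamma(16),
              0)
  peak <- 5^5 * exp(-5) / gamma(6) - ratio * 5^15 * exp(-5) / gamma(16)
  h / peak
}

#' @rdname double_gamma_hrf
#' @return `hrf_peak_lag`: the kernel's peak time in seconds (numerically
#'   located; ~5 s for the default shape).
#' @export
hrf_peak_lag <- function(ratio = 1 / 6) {
  t <- seq(0, 20, by = 0.01)
  t[which.max(double_gamma_hrf(t, ratio))]
}

erd_depth_for_hand <- function(profile, hand) {
  depth <- profile$erd_depth
  impaired <- (hand == "left" && profile$laterality == "left_impaired") ||
    (hand == "right" && profile$laterality == "right_impaired")
  if (impaired) depth * profile$impair_factor else depth
}

#' Generate one synthetic hybrid-recording subject
#'
#' Produces a paired EEG + fNIRS [subject_dataset()] for the given paradigm.
#' Each EEG trial is 1/f background noise plus alpha (band centre) and beta
#' (20 Hz) oscillations weighted by the sensorimotor spatial pattern; on the
#' hemisphere contralateral to the imagined hand the oscillation amplitude is
#' multiplied by `(1 - erd_depth)` during the task window (0.5 s onset ramp).
#' Each fNIRS trial carries a double-gamma HbO response (onset `hemo_delay`
#' after task onset) on contralateral channels, `-0.3 x` scaled HbR, a slow
#' 0.1 Hz physiological oscillation and white noise. Labels alternate across
#' the session schedule. Deterministic per seed; the planted parameters are
#' recoverable with [planted_truth()].
#'
#' @param profile A [subject_profile()].
#' @param paradigm A [paradigm_spec()].
#' @param n_channels_eeg,n_channels_fnirs Channel counts (defaults 30 / 36,
#'   the canonical network input shapes).
#' @param fs_eeg,fs_fnirs Sampling rates (Hz).
#' @param subject_id Identifier.
#' @param seed RNG seed.
#' @param cohort_tag Cohort annotation.
#' @return A [subject_dataset()]; `extras` holds the pre-stimulus EEG
#'   baseline segments (`eeg_prestim`) and the planted truth record.
#' @export
generate_subject <- function(profile, paradigm = paradigm_spec(),
                             n_channels_eeg = 30, n_channels_fnirs = 36,
                             fs_eeg = 200, fs_fnirs = 10,
                             subject_id = "S01", seed = 1L,
                             cohort_tag = if (profile$laterality == "normal")
                               "normal" else "patient") {
  pat_e <- profile$spatial_pattern %||% default_spatial_pattern(n_channels_eeg)
  if (!any(pat_e$left > 0) || !any(pat_e$right > 0))
    stopf("spatial pattern needs at least one non-zero channel per hemisphere")
  if (length(pat_e$left) > n_channels_eeg)
    stopf("spatial pattern requires %d channels, only %d available",
          length(pat_e$left), n_channels_eeg)
  half_n <- n_channels_fnirs %/% 2
  pat_pair <- default_spatial_pattern(half_n)

  n_tr <- n_trials_total(paradigm)
  # alternating, session-balanced schedule (counterbalanced cue order)
  labels <- unlist(lapply(seq_len(paradigm$n_sessions), function(s) {
    base <- rep(c(0L, 1L), paradigm$trials_per_class_per_session)
    if (s %% 2 == 0) 1L - base else base
  }))

  pre_s <- 3
  task_on <- pre_s + paradigm$cue_duration_s
  len_e <- round((task_on + paradigm$task_duration_s) * fs_eeg)
  n_task_e <- round(paradigm$task_duration_s * fs_eeg)
  n_pre_e <- round(pre_s * fs_eeg)
  t_e <- (seq_len(len_e) - 1) / fs_eeg
  f_alpha <- mean(profile$erd_band)
  f_beta <- 20
  amp_alpha <- 1
  amp_beta <- 0.5
  ramp <- pmin(pmax((t_e - task_on) / 0.5, 0), 1)  # 0.5 s onset ramp

  len_n <- round((task_on + paradigm$task_duration_s) * fs_fnirs)
  n_task_n <- floor(paradigm$task_duration_s * fs_fnirs)
  t_n <- (seq_len(len_n) - 1) / fs_fnirs

  eeg <- array(0, dim = c(n_tr, n_channels_eeg, n_task_e))
  pre <- array(0, dim = c(n_tr, n_channels_eeg, n_pre_e))
  nirs <- array(0, dim = c(n_tr, n_channels_fnirs, n_task_n))
  phases <- depths <- numeric(n_tr)

  with_seed(seed, {
    for (i in seq_len(n_tr)) {
      hand <- paradigm$classes[labels[i] + 1]
      depth <- erd_depth_for_hand(profile, hand)
      depths[i] <- depth
      # contralateral hemisphere weights
      contra <- if (hand == "left") pat_e$right else pat_e$left
      ipsi <- if (hand == "left") pat_e$left else pat_e$right
      phases[i] <- stats::runif(1, 0, 2 * pi)
      osc <- amp_alpha * sin(2 * pi * f_alpha * t_e + phases[i]) +
        amp_beta * sin(2 * pi * f_beta * t_e + phases[i] * 1.7)
      mod <- 1 - depth * ramp
      trial <- matrix(0, n_channels_eeg, len_e)
      for (ch in seq_len(n_channels_eeg)) {
        w <- contra[ch] * mod + ipsi[ch]
        trial[ch, ] <- osc * w +
          profile$snr * amp_alpha * pink_noise(len_e, fs_eeg)
      }
      eeg[i, , ] <- trial[, len_e - n_task_e + seq_len(n_task_e)]
      pre[i, , ] <- trial[, seq_len(n_pre_e)]

      # channels: first half HbO, second half mirrored HbR, each half split
      # into left / right hemisphere optode groups
      contra_pair <- if (hand == "left") pat_pair$right else pat_pair$left
      hrf <- double_gamma_hrf(t_n - task_on - profile$hemo_delay)
      physio_phase <- stats::runif(1, 0, 2 * pi)
      trial_n <- matrix(0, n_channels_fnirs, len_n)
      for (ch in seq_len(n_channels_fnirs)) {
        j <- if (ch <= half_n) ch else ch - half_n
        chromo <- if (ch <= half_n) 1 else -0.3
        resp <- chromo * profile$hemo_gain * contra_pair[j] * hrf
        physio <- 0.2 * profile$hemo_gain *
          sin(2 * pi * 0.1 * t_n + physio_phase + ch)
        noise <- 0.2 * profile$hemo_gain * profile$snr * stats::rnorm(len_n)
        trial_n[ch, ] <- resp + physio + noise
      }
      nirs[i, , ] <- trial_n[, len_n - n_task_n + seq_len(n_task_n)]
    }
  })

  half_e <- n_channels_eeg %/% 2
  ch_eeg <- c(paste0("L", sprintf("%02d", seq_len(half_e))),
              paste0("R", sprintf("%02d", seq_len(n_channels_eeg - half_e))))
  ch_nirs <- c(paste0("HbO", sprintf("%02d", seq_len(half_n))),
               paste0("HbR", sprintf("%02d", seq_len(n_channels_fnirs - half_n))))

  ts_e <- trial_set(subject_id, "EEG", eeg, labels, fs_eeg, ch_eeg,
                    paradigm$classes)
  ts_n <- trial_set(subject_id, "FNIRS", nirs, labels, fs_fnirs,
                    ch_nirs, paradigm$classes)
  truth <- list(
    truth_erd_depth = profile$erd_depth,
    truth_trial_depth = depths,
    truth_erd_band = profile$erd_band,
    truth_hemo_gain = profile$hemo_gain,
    truth_hemo_delay = profile$hemo_delay,
    truth_snr = profile$snr,
    truth_phases = phases,
    truth_labels = as.numeric(labels),
    truth_laterality = match(profile$laterality,
                             c("normal", "left_impaired", "right_impaired")),
    truth_hrf_peak_lag = hrf_peak_lag(),
    truth_alpha_freq = f_alpha,
    truth_pattern_left = pat_e$left,
    truth_pattern_right = pat_e$right
  )
  subject_dataset(subject_id, ts_e, ts_n,
                  cohort_tag = cohort_tag,
                  extras = c(list(eeg_prestim = pre), truth))
}

#' Planted ground truth of a generated subject
#'
#' Returns the exact generative parameters used for a subject produced by
#' [generate_subject()], enabling parameter-recovery tests (ERD power-ratio
#' estimation, hemodynamic peak timing). Errors on datasets this module did
#' not generate.
#'
#' @param sd A [subject_dataset()] from [generate_subject()].
#' @return Named list of planted parameters; `expected_alpha_power_ratio` is
#'   the analytic task/baseline alpha-power ratio `(1 - erd_depth)^2` on a
#'   fully modulated contralateral channel.
#' @export
planted_truth <- function(sd) {
  ex <- sd$extras
  if (is.null(ex$truth_erd_depth))
    stopf("subject '%s' carries no planted-truth record (foreign dataset)",
          sd$subject_id)
  list(erd_depth = as.numeric(ex$truth_erd_depth),
       trial_depth = as.numeric(ex$truth_trial_depth),
       erd_band = as.numeric(ex$truth_erd_band),
       hemo_gain = as.numeric(ex$truth_hemo_gain),
       hemo_delay = as.numeric(ex$truth_hemo_delay),
       snr = as.numeric(ex$truth_snr),
       phases = as.numeric(ex$truth_phases),
       labels = as.integer(ex$truth_labels),
       laterality = c("normal", "left_impaired",
                      "right_impaired")[as.integer(ex$truth_laterality)],
       hrf_peak_lag = as.numeric(ex$truth_hrf_peak_lag),
       alpha_freq = as.numeric(ex$truth_alpha_freq),
       pattern_left = as.numeric(ex$truth_pattern_left),
       pattern_right = as.numeric(ex$truth_pattern_right),
       expected_alpha_power_ratio = (1 - as.numeric(ex$truth_erd_depth))^2)
}

#' Population-level generative specification
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param fraction_patient Fraction of patient-like (impaired-ERD) subjects.
#' @param paradigm A [paradigm_spec()].
#' @param erd_depth_mean,erd_depth_sd Population distribution of ERD depth
#'   (truncated normal on `[0, 1]`).
#' @param snr_mean,snr_sd Background-to-signal ratio distribution.
#' @param hemo_gain_mean,hemo_gain_sd,hemo_delay_mean,hemo_delay_sd
#'   Hemodynamic response distributions.
#' @param n_channels_eeg,n_channels_fnirs,fs_eeg,fs_fnirs Recording geometry.
#' @param master_seed Master seed; per-subject seeds are derived from it.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 6, fraction_patient = 0,
                            paradigm = paradigm_spec(),
                            erd_depth_mean = 0.6, erd_depth_sd = 0.15,
                            snr_mean = 0.5, snr_sd = 0.1,
                            hemo_gain_mean = 1, hemo_gain_sd = 0.3,
                            hemo_delay_mean = 2, hemo_delay_sd = 0.5,
                            n_channels_eeg = 30, n_channels_fnirs = 36,
                            fs_eeg = 200, fs_fnirs = 10,
                            master_seed = 1L) {
  if (n_subjects < 2) stopf("n_subjects must be >= 2")
  if (fraction_patient < 0 || fraction_patient > 1)
    stopf("fraction_patient must lie in [0, 1]")
  structure(as.list(environment()), class = "population_spec")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic population
#'
#' Draws per-subject profiles i.i.d. from the population distributions of a
#' [population_spec()] and generates each subject with a deterministically
#' derived seed. The first `round(fraction_patient * n)` subjects (after a
#' seeded shuffle) are patient-like, with impaired laterality alternating
#' left / right.
#'
#' @param pspec A [population_spec()].
#' @return Named list of [subject_dataset()]s (`S01`, `S02`, ...).
#' @export
generate_population <- function(pspec) {
  n <- pspec$n_subjects
  n_pat <- round(pspec$fraction_patient * n)
  profiles <- with_seed(pspec$master_seed, {
    is_pat <- seq_len(n) %in% sample.int(n, n_pat)
    lapply(seq_len(n), function(i) {
      subject_profile(
        erd_depth = clamp(stats::rnorm(1, pspec$erd_depth_mean,
                                       pspec$erd_depth_sd), 0, 1),
        hemo_gain = max(0.2, stats::rnorm(1, pspec$hemo_gain_mean,
                                          pspec$hemo_gain_sd)),
        hemo_delay = clamp(stats::rnorm(1, pspec$hemo_delay_mean,
                                        pspec$hemo_delay_sd), 0.5, 4),
        snr = clamp(stats::rnorm(1, pspec$snr_mean, pspec$snr_sd), 0.2, 1.5),
        spatial_pattern = default_spatial_pattern(
          pspec$n_channels_eeg, jitter = stats::runif(1, -1, 1)),
        laterality = if (!is_pat[i]) "normal" else
          c("left_impaired", "right_impaired")[(i %% 2) + 1]
      )
    })
  })
  pop <- lapply(seq_len(n), function(i) {
    generate_subject(profiles[[i]], pspec$paradigm,
                     n_channels_eeg = pspec$n_channels_eeg,
                     n_channels_fnirs = pspec$n_channels_fnirs,
                     fs_eeg = pspec$fs_eeg, fs_fnirs = pspec$fs_fnirs,
                     subject_id = sprintf("S%02d", i),
                     seed = derive_seed(pspec$master_seed, i))
  })
  stats::setNames(pop, vapply(pop, function(s) s$subject_id, character(1)))
}
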