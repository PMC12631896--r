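test_that("EEG preprocessing yields the canonical trial geometry", {
  # 10 s task recorded at 256 Hz -> 2000 samples per trial at 200 Hz
  fs <- 256
  rec <- sine_recording(freqs = 10, amps = 1, fs = fs, n_trials = 4)
  ts <- preprocess_eeg(rec, tiny_paradigm(), target_fs = 200)
  expect_equal(dim(ts$data), c(4, 2, 2000))
  expect_equal(ts$fs, 200)
  expect_identical(ts$labels, c(0L, 1L, 0L, 1L))
})

test_that("baseline correction removes a constant offset", {
  fs <- 256
  rec <- sine_recording(freqs = 10, amps = 1, fs = fs, n_trials = 3)
  offset <- 5e3
  rec$data[1, ] <- rec$data[1, ] + offset
  # band includes DC so the offset survives filtering and must be removed by
  # the pre-stimulus baseline subtraction alone
  ts <- preprocess_eeg(rec, tiny_paradigm(), target_fs = 200, band = c(0, 50))
  expect_lt(max(abs(rowMeans(ts$data[, 1, ]))), 1e-9 * offset)
})

test_that("out-of-band interference is attenuated by >= 20 dB", {
  fs <- 256
  rec_in <- sine_recording(freqs = 10, amps = 1, fs = fs, n_trials = 3)
  rec_out <- sine_recording(freqs = 80, amps = 1, fs = fs, n_trials = 3)
  ts_in <- preprocess_eeg(rec_in, tiny_paradigm(), target_fs = 200)
  ts_out <- preprocess_eeg(rec_out, tiny_paradigm(), target_fs = 200)
  rms <- function(x) sqrt(mean(x^2))
  atten_db <- 20 * log10(rms(ts_in$data[1, 1, ]) / rms(ts_out$data[1, 1, ]))
  expect_gte(atten_db, 20)
})

test_that("preprocessing errors are explicit", {
  fs <- 80  # below Nyquist for a 50 Hz band edge
  rec <- sine_recording(freqs = 10, amps = 1, fs = fs, n_trials = 2)
  expect_error(preprocess_eeg(rec, tiny_paradigm(), target_fs = 200),
               "Nyquist")
  # event whose task window runs past the record end
  fs <- 256
  rec <- sine_recording(freqs = 10, amps = 1, fs = fs, n_trials = 2)
  rec$events <- rbind(rec$events,
                      data.frame(sample = ncol(rec$data) - fs,
                                 label = "left"))
  expect_error(preprocess_eeg(rec, tiny_paradigm(), target_fs = 200),
               "outside the")
})

test_that("preprocessing is linear in its input", {
  fs <- 128
  set.seed(5)
  base <- sine_recording(freqs = c(4, 11), amps = c(1, 1), fs = fs,
                         n_trials = 2, extra_noise = 0.5)
  recx <- base
  recy <- base
  set.seed(6)
  recy$data <- matrix(rnorm(length(base$data)), nrow(base$data))
  a <- 1.7; b <- -0.6
  mix <- base
  mix$data <- a * recx$data + b * recy$data
  p <- function(r) preprocess_eeg(r, tiny_paradigm(), target_fs = 64,
                                  band = c(0.5, 25))$data
  expect_equal(p(mix), a * p(recx) + b * p(recy), tolerance = 1e-9)
})

test_that("Beer-Lambert inversion recovers planted chromophore dynamics", {
  fs <- 10
  n <- 3000
  t <- (seq_len(n) - 1) / fs
  hbo <- 1.0 * sin(2 * pi * 0.05 * t)
  hbr <- -0.5 * sin(2 * pi * 0.05 * t + 0.4)
  ext <- default_extinction_table()
  e760 <- ext[ext$wavelength == 760, ]
  e850 <- ext[ext$wavelength == 850, ]
  d <- 3; dpf <- c(6, 6)
  od1 <- (e760$eps_hbo * hbo + e760$eps_hbr * hbr) * d * dpf[1]
  od2 <- (e850$eps_hbo * hbo + e850$eps_hbr * hbr) * d * dpf[2]
  ev <- data.frame(sample = c(500, 1500), label = c("left", "right"))
  rec <- continuous_recording(rbind(od1, od2), fs, ev,
                              wavelengths = c(760, 850))
  out <- beer_lambert(rec)
  expect_equal(out$data[1, ], hbo, tolerance = 1e-10)
  expect_equal(out$data[2, ], hbr, tolerance = 1e-10)

  # zero optical density -> zero concentrations (homogeneous system)
  rec0 <- rec; rec0$data[] <- 0
  expect_true(all(beer_lambert(rec0)$data == 0))

  # swapping wavelength blocks together with extinction rows is a no-op
  rec_sw <- rec
  rec_sw$data <- rbind(od2, od1)
  rec_sw$wavelengths <- c(850, 760)
  out_sw <- beer_lambert(rec_sw)
  expect_equal(unname(out_sw$data), unname(out$data), tolerance = 1e-12)

  # a singular extinction system must be refused
  rec_bad <- rec; rec_bad$wavelengths <- c(760, 760)
  expect_error(beer_lambert(rec_bad), "singular")
  rec_bad2 <- rec; rec_bad2$wavelengths <- c(760, 555)
  expect_error(beer_lambert(rec_bad2), "extinction")
})

test_that("fNIRS band-pass suppresses slow drift and supports resampling", {
  fs <- 10
  par <- tiny_paradigm()
  n <- 2200
  drift <- seq(0, 50, length.out = n)
  hemo <- sin(2 * pi * 0.05 * (seq_len(n) - 1) / fs)
  ev <- data.frame(sample = c(400, 700, 1000, 1300),
                   label = rep(c("left", "right"), 2))
  rec <- continuous_recording(rbind(drift + hemo, drift + hemo), fs, ev)
  ts <- preprocess_fnirs(rec, par)
  expect_equal(dim(ts$data)[3], 100)  # 10 s x 10 Hz
  # compare against raw epoching without the filter: drift inflates variance
  raw <- rec$data[1, ]
  raw_trials <- sapply(ev$sample, function(s) raw[s + 20 + 0:99])
  expect_lt(mean(apply(ts$data[, 1, ], 1, var)), mean(apply(raw_trials, 2, var)))

  # resample-to-length reproduces the canonical 100-sample input exactly
  ts2 <- preprocess_fnirs(rec, par, resample_to = 50)
  expect_equal(dim(ts2$data)[3], 50)
  expect_equal(ts2$fs, 5)

  # zero in -> zero out (linearity)
  rec0 <- rec; rec0$data[] <- 0
  expect_true(all(abs(preprocess_fnirs(rec0, par)$data) < 1e-12))

  # too-short pre-event baseline is refused
  rec_short <- rec
  rec_short$events$sample[1] <- 10
  expect_error(preprocess_fnirs(rec_short, par), "baseline")
})
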