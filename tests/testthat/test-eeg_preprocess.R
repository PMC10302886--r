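test_that("bandpass passes in-band tones and removes DC", {
  fs <- 256
  tt <- (seq_len(8 * fs) - 1) / fs
  x <- sin(2 * pi * 10 * tt)
  y <- bandpass(x, 1, 45, fs = fs)
  core <- seq(fs / 2, length(y) - fs / 2)  # discard 0.5 s edges
  amp <- sqrt(2 * mean(y[core]^2))
  expect_equal(amp, 1, tolerance = 0.05)

  # the 1 Hz high-pass edge has a seconds-long transient: use a long record
  ydc <- bandpass(rep(2, 20 * fs), 1, 45, fs = fs)
  core_dc <- seq(5 * fs, length(ydc) - 5 * fs)
  expect_lt(abs(mean(ydc[core_dc])), 1e-3)
})

test_that("out-of-band tones are attenuated as the filter response predicts", {
  fs <- 256
  tt <- (seq_len(8 * fs) - 1) / fs
  x60 <- sin(2 * pi * 60 * tt)
  y <- bandpass(x60, 1, 45, fs = fs)
  core <- seq(fs, length(y) - fs)
  atten_db <- 20 * log10(sqrt(mean(x60[core]^2)) / sqrt(mean(y[core]^2)))
  expect_gte(atten_db, 20)
  # oracle: squared magnitude of the forward-backward Butterworth at 60 Hz,
  # evaluated directly from the transfer-function polynomials
  flt <- signal::butter(3, c(1, 45) / (fs / 2), type = "pass")
  w <- 2 * pi * 60 / fs
  ej <- exp(-1i * w * (seq_along(flt$b) - 1))
  H <- sum(flt$b * ej) / sum(flt$a * exp(-1i * w * (seq_along(flt$a) - 1)))
  pred_db <- -20 * log10(Mod(H)^2)  # two passes
  expect_equal(atten_db, pred_db, tolerance = 0.15 * abs(pred_db))
})

test_that("band edges outside (0, fs/2) are rejected", {
  expect_error(bandpass(rnorm(100), 0, 45, fs = 100), class = "lcasonify_param_error")
  expect_error(bandpass(rnorm(100), 1, 60, fs = 100), class = "lcasonify_param_error")
})

test_that("montage presets drop the documented channels", {
  arr <- array(rnorm(2 * 19 * 64), c(2, 19, 64))
  eeg <- eeg_epochs(arr, 64, montage_1020(), c("HAPV", "LANV"))
  expect_equal(dim(drop_channels(eeg, "E17"))[2], 17)
  expect_equal(dim(drop_channels(eeg, "E14"))[2], 14)
  expect_false(any(c("O1", "O2") %in% drop_channels(eeg, "E17")$channel_names))
  expect_identical(drop_channels(eeg, character(0)), eeg)
  expect_error(drop_channels(eeg, "XX"), class = "lcasonify_param_error")
})

test_that("common-average referencing zeroes the channel sum and is idempotent", {
  arr <- array(rnorm(3 * 5 * 50), c(3, 5, 50))
  eeg <- eeg_epochs(arr, 50, paste0("Ch", 1:5), rep("HAPV", 3))
  ref <- common_average_reference(eeg)
  sums <- apply(ref$data, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-9)
  ref2 <- common_average_reference(ref)
  expect_equal(ref2$data, ref$data, tolerance = 1e-12)

  # a (+v, -v) pair already has zero mean
  v <- rnorm(50)
  arr2 <- array(0, c(1, 2, 50))
  arr2[1, 1, ] <- v
  arr2[1, 2, ] <- -v
  two <- eeg_epochs(arr2, 50, c("A", "B"), "HAPV")
  expect_equal(common_average_reference(two)$data, two$data, tolerance = 1e-12)

  one <- eeg_epochs(array(rnorm(50), c(1, 1, 50)), 50, "A", "HAPV")
  expect_error(common_average_reference(one), class = "lcasonify_param_error")
})

test_that("resampling rescales the sample count and keeps in-band content", {
  fs <- 1000
  tt <- (seq_len(12 * fs) - 1) / fs
  arr <- array(sin(2 * pi * 5 * tt), c(1, 1, 12 * fs))
  eeg <- eeg_epochs(arr, fs, "Cz", "HAPV")
  out <- resample_epochs(eeg, 80)
  expect_equal(dim(out)[3], 960)
  core <- 80:880
  amp <- sqrt(2 * mean(out$data[1, 1, core]^2))
  expect_equal(amp, 1, tolerance = 0.05)
  expect_error(resample_epochs(eeg, 2000), class = "lcasonify_param_error")
})

test_that("halving the rate suppresses content above the new Nyquist", {
  fs <- 64
  tt <- (seq_len(12 * fs) - 1) / fs
  tone <- sin(2 * pi * 22 * tt)  # above fs/4 = 16 Hz
  eeg <- eeg_epochs(array(tone, c(1, 1, length(tone))), fs, "Cz", "HAPV")
  out <- resample_epochs(eeg, 32)
  core <- 32:(dim(out)[3] - 32)
  atten_db <- 20 * log10(sqrt(mean(tone^2)) / sqrt(mean(out$data[1, 1, core]^2)))
  expect_gte(atten_db, 20)
})

test_that("the window grid obeys the counting formula", {
  taus <- c(12, 6, 3, 1.5, 0.75, 0.375)
  counts <- sapply(taus, function(tau) window_grid(tau, 12)$n_windows)
  expect_equal(counts, floor((12 - taus) / (taus * 0.5)) + 1)
  expect_equal(window_grid(3, 12)$n_windows, 7L)
  expect_equal(window_grid(12, 12)$n_windows, 1L)
  expect_error(window_grid(13, 12), class = "lcasonify_param_error")
})

test_that("window segments are Hann-tapered with peak one at the midpoint", {
  fs <- 32
  x <- matrix(1, 2, 12 * fs)
  segs <- window_segments(x, window_grid(3, 12), fs)
  expect_length(segs, 7L)
  wlen <- 3 * fs
  expect_true(all(vapply(segs, ncol, integer(1)) == wlen))
  # constant input: the segment midpoint equals the taper midpoint (peak 1)
  expect_equal(segs[[1]][1, wlen / 2 + 1], 1, tolerance = 1e-12)
  expect_equal(segs[[1]][1, 1], 0, tolerance = 1e-12)
})

test_that("the conditioning chain preserves labels and trial order", {
  spec <- coupled_eeg_spec(seed = 1, n_trials = 6, fs = 256)
  eeg <- gen_eeg_trials(spec)
  out <- preprocess_eeg(eeg, montage = "E17", fs_out = 64)
  expect_identical(out$labels, eeg$labels)
  expect_equal(out$fs, 64)
  expect_equal(dim(out)[2], 6)  # montage has no O1/O2 beyond the preset's
  sums <- apply(out$data, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-6)  # referencing happened before resampling
})
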