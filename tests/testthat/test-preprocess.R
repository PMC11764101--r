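test_that("band-pass filter preserves the passband and rejects the stopband", {
  fs <- 100
  t <- (0:999) / fs
  cfg <- preprocess_config(band = c(8, 30), filter_order = 5L)
  inband <- sin(2 * pi * 20 * t)
  y <- bandpass_filter(inband, fs, cfg)
  core <- 51:950 # discard 0.5 s edges
  expect_lt(abs(max(abs(y[core])) / max(abs(inband)) - 1), 0.01)
  out <- sin(2 * pi * 50 * t * 0.999) # near 50 Hz line frequency
  y2 <- bandpass_filter(out, fs, cfg)
  expect_lt(sqrt(mean(y2[core]^2)) / sqrt(mean(out^2)), 0.05)
})

test_that("filtering is zero-phase and linear", {
  fs <- 100
  cfg <- preprocess_config()
  imp <- c(rep(0, 300), 1, rep(0, 300))
  y <- bandpass_filter(imp, fs, cfg)
  # impulse response of a zero-phase filter is symmetric about the impulse
  k <- 60
  expect_equal(y[301 + 1:k], y[301 - 1:k], tolerance = 1e-9)
  set.seed(1)
  a <- rnorm(500); b <- rnorm(500)
  lhs <- bandpass_filter(2 * a - 3 * b, fs, cfg)
  rhs <- 2 * bandpass_filter(a, fs, cfg) - 3 * bandpass_filter(b, fs, cfg)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("invalid filter configurations error", {
  expect_error(bandpass_filter(rnorm(500), fs = 50, preprocess_config(band = c(8, 30))),
               "Nyquist")
  expect_error(bandpass_filter(rnorm(10), fs = 100, preprocess_config()),
               "too short")
  expect_error(preprocess_config(band = c(30, 8)))
  expect_error(preprocess_config(filter_order = 0L))
})

test_that("epoch extraction cuts half-open 0-based windows", {
  fs <- 100
  cont <- matrix(seq_len(2 * 1000), nrow = 2, byrow = TRUE)
  ev <- data.frame(onset_sample = 0L, label = 0L)
  ep <- extract_epochs(cont, fs, ev, preprocess_config(epoch_window = c(0, 1)))
  expect_equal(dim(ep$data), c(1L, 2L, 100L))
  expect_equal(ep$data[1, 1, ], as.numeric(1:100)) # samples [0, 100)
  # study window: 0.5 to 3.5 s at 100 Hz -> 300 samples
  ev2 <- data.frame(onset_sample = c(0L, 100L), label = c(0L, 1L))
  ep2 <- extract_epochs(cont, fs, ev2, preprocess_config(epoch_window = c(0.5, 3.5)))
  expect_equal(dim(ep2$data)[3], 300L)
  expect_equal(ep2$data[2, 1, 1], cont[1, 151]) # onset 100 + 50, 0-based
  ev_bad <- data.frame(onset_sample = c(0L, 980L), label = c(0L, 1L))
  expect_error(extract_epochs(cont, fs, ev_bad, preprocess_config(epoch_window = c(0, 1))),
               "event\\(s\\): 2")
})

test_that("filtering before epoching matches epoching then filtering on interior samples", {
  fs <- 100
  set.seed(7)
  cont <- matrix(rnorm(2 * 2000), nrow = 2)
  cfg <- preprocess_config(epoch_window = c(0, 4))
  ev <- data.frame(onset_sample = c(500L, 1000L), label = c(0L, 1L))
  a <- extract_epochs(bandpass_filter(cont, fs, cfg), fs, ev, cfg)
  b <- bandpass_filter(extract_epochs(cont, fs, ev, cfg), cfg = cfg)
  core <- 101:300 # interior, away from epoch-edge transients
  expect_equal(a$data[, , core], b$data[, , core], tolerance = 1e-2)
})

test_that("EDF round-trips continuous data within quantization error", {
  fs <- 100L
  set.seed(3)
  cont <- matrix(rnorm(3 * 200, sd = 20), nrow = 3)
  rownames(cont) <- c("C3", "Cz", "C4")
  path <- tempfile(fileext = ".edf")
  write_edf(cont, fs, path)
  back <- read_edf(path)
  expect_equal(back$fs, 100)
  expect_equal(back$channel_names, c("C3", "Cz", "C4"))
  expect_equal(unname(back$data[, 1:200]), unname(cont), tolerance = 1e-3)
  expect_error(suppressWarnings(read_edf(tempfile())), regexp = ".")
})

test_that("epoch container validates its invariants and round-trips to disk", {
  expect_error(epoched_eeg(array(0, c(3, 2, 10)), labels = 1:2, fs = 10),
               "length\\(labels\\)")
  expect_error(epoched_eeg(array(NA_real_, c(2, 2, 10)), labels = 0:1, fs = 10),
               "non-finite")
  expect_error(epoched_eeg(array(0, c(2, 2, 10)), labels = 0:1, fs = 10,
                           window = c(0, 2)), "inconsistent")
  ep <- noise_epochs()
  prefix <- tempfile()
  write_epochs(ep, prefix)
  back <- read_epochs(prefix)
  expect_equal(back$data, ep$data, tolerance = 1e-12)
  expect_identical(back$labels, ep$labels)
  expect_equal(back$window, ep$window)
})
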