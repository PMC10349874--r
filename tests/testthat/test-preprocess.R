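make_rec <- function(n = 256, fs = 64, labels = c("C3", "C4", "ECG")) {
  set.seed(1234)
  mc_recording(lapply(labels, function(l)
    sampled_signal(round(rnorm(n), 6), fs, l)))
}

test_that("csv recordings round trip through the standard dialect", {
  rec <- make_rec()
  path <- tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- load_recording(path, fs = 64)
  expect_identical(names(back$channels), names(rec$channels))
  for (l in names(rec$channels))
    expect_equal(back$channels[[l]]$values, rec$channels[[l]]$values)
  # a leading time column is auto-dropped
  path2 <- tempfile(fileext = ".csv")
  write_recording(rec, path2, time_column = TRUE)
  back2 <- load_recording(path2, fs = 64,
                          group_map = list(EEG = c("C3", "C4"), ECG = "ECG"))
  expect_length(back2$channels, 3)
  expect_identical(role_labels(back2, "EEG"), c("C3", "C4"))
  # tab-delimited input is detected
  path3 <- tempfile(fileext = ".tsv")
  df <- as.data.frame(lapply(rec$channels, `[[`, "values"))
  utils::write.table(df, path3, sep = "\t", row.names = FALSE)
  expect_equal(load_recording(path3, fs = 64)$channels[["C3"]]$values,
               rec$channels[["C3"]]$values)
})

test_that("malformed csv input fails with located errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3,oops", "5,6"), path)
  expect_error(load_recording(path, fs = 10), "row 2, column 'b'")
  expect_error(load_recording(path), "'fs' must be supplied")
  expect_error(load_recording(tempfile(), fs = 10), "not found")
  path2 <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3,", "5,6"), path2)
  expect_error(load_recording(path2, fs = 10), "row 2, column 'b'")
})

test_that("edf recordings round trip within quantization error", {
  rec <- make_rec(n = 200, fs = 100)
  path <- tempfile(fileext = ".edf")
  csdea:::write_edf(rec, path, record_dur = 1)
  back <- load_recording(path)
  expect_equal(back$fs, 100)
  expect_identical(names(back$channels), names(rec$channels))
  for (l in names(rec$channels)) {
    v <- rec$channels[[l]]$values
    tol <- (max(v) - min(v)) / 65534 * 2 + 1e-6
    expect_lt(max(abs(back$channels[[l]]$values[1:200] - v)), tol)
  }
})

test_that("the high-pass removes DC and passes in-band tones", {
  fs <- 512
  const <- sampled_signal(rep(7.3, 10 * fs), fs)
  hp <- highpass_zero_phase(const, 1)
  core <- hp$values[(2 * fs):(8 * fs)]
  expect_lt(max(abs(core)), 0.01 * 7.3)
  tone <- sampled_signal(sin(2 * pi * 10 * (0:(10 * fs - 1)) / fs), fs)
  hp2 <- highpass_zero_phase(tone, 1)
  central <- hp2$values[(fs + 1):(9 * fs)]
  expect_lt(max(abs(central - tone$values[(fs + 1):(9 * fs)])), 0.02)
  zeros <- highpass_zero_phase(sampled_signal(rep(0, 2048), fs), 1)
  expect_equal(zeros$values, rep(0, 2048))
  expect_error(highpass_zero_phase(tone, 300), "Nyquist")
})

test_that("the low-pass passes DC and stops far-out-of-band tones", {
  fs <- 512
  const <- sampled_signal(rep(4.2, 10 * fs), fs)
  lp <- lowpass_zero_phase(const, 2)
  core <- lp$values[(2 * fs):(8 * fs)]
  expect_lt(max(abs(core - 4.2)), 0.01 * 4.2)
  t <- (0:(10 * fs - 1)) / fs
  hum <- sampled_signal(sin(2 * pi * 50 * t), fs)
  lp2 <- lowpass_zero_phase(hum, 2)
  expect_lt(max(abs(lp2$values[(2 * fs):(8 * fs)])), 0.05)
  # superposition: the 0.5 Hz component survives alone
  mix <- sampled_signal(sin(2 * pi * 0.5 * t) + sin(2 * pi * 50 * t), fs)
  lp3 <- lowpass_zero_phase(mix, 2)
  idx <- (2 * fs):(8 * fs)
  rms_err <- sqrt(mean((lp3$values[idx] - sin(2 * pi * 0.5 * t[idx]))^2))
  expect_lt(rms_err, 0.05 * sqrt(0.5))
})

test_that("filtering is zero-phase: output peaks align with the input", {
  fs <- 256
  t <- (0:(8 * fs - 1)) / fs
  x <- sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 11 * t)
  hp <- highpass_zero_phase(sampled_signal(x, fs), 1)
  cc <- stats::ccf(hp$values, x, lag.max = 20, plot = FALSE)
  expect_lte(abs(cc$lag[which.max(cc$acf)]), 1)
})

test_that("average re-referencing zeroes the role-group sum and is idempotent", {
  x <- rnorm(100); y <- rnorm(100); z <- rnorm(100)
  rec <- mc_recording(list(sampled_signal(x, 10, "e1"),
                           sampled_signal(y, 10, "e2"),
                           sampled_signal(z, 10, "ecg")),
                      groups = list(EEG = c("e1", "e2"), ECG = "ecg"))
  rr <- rereference_average(rec)
  expect_equal(rr$channels$e1$values, (x - y) / 2)
  expect_equal(rr$channels$e2$values, (y - x) / 2)
  expect_equal(rr$channels$ecg$values, z)   # non-role untouched
  expect_equal(rr$channels$e1$values + rr$channels$e2$values, rep(0, 100))
  rr2 <- rereference_average(rr)
  expect_equal(rr2$channels$e1$values, rr$channels$e1$values)
  # identical channels cancel to zero
  rec2 <- mc_recording(list(sampled_signal(x, 10, "a"),
                            sampled_signal(x, 10, "b")),
                       groups = list(EEG = c("a", "b")))
  expect_equal(rereference_average(rec2)$channels$a$values, rep(0, 100))
  rec3 <- mc_recording(list(sampled_signal(x, 10, "a")),
                       groups = list(EEG = "a"))
  expect_error(rereference_average(rec3), "at least 2")
})

test_that("decimation keeps DC, halves rates exactly, and preserves tones", {
  fs <- 2048
  sig <- sampled_signal(rep(2.5, fs * 10), fs)
  expect_identical(downsample(sig, 1), sig)
  d4 <- downsample(sig, 4)
  expect_equal(d4$fs, 512)
  expect_length(d4$values, 512 * 10)
  core <- d4$values[200:4800]
  expect_lt(max(abs(core - 2.5)), 0.01 * 2.5)
  expect_error(downsample(sig, 2.5), "positive integer")
  # a 10 Hz tone at 2048 Hz survives decimation to 512 Hz at 10 Hz
  t <- (0:(fs * 10 - 1)) / fs
  tone <- downsample(sampled_signal(sin(2 * pi * 10 * t), fs), 4)
  spec <- Mod(stats::fft(tone$values * signal::hanning(length(tone$values))))
  freqs <- (seq_along(spec) - 1) * 512 / length(spec)
  half <- seq_len(length(spec) / 2)
  expect_lt(abs(freqs[half][which.max(spec[half])] - 10), 0.15)
})
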