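test_that("low-pass filter implements the integer-coefficient recurrence", {
  expect_equal(lowpass_filter(numeric(50)), numeric(50))
  set.seed(1)
  x <- rnorm(300)
  expect_lt(max(abs(lowpass_filter(x) - lowpass_recurrence_oracle(x))), 1e-9)
  # DC gain: steady state of the unit step is 36
  step <- rep(1, 100)
  expect_equal(tail(lowpass_filter(step), 1), 36)
  # impulse response equals the FIR equivalent (1 - z^-6)^2 / (1 - z^-1)^2,
  # i.e. the 6-sample boxcar convolved with itself
  h <- lowpass_filter(c(1, numeric(30)))
  fir <- convolve(rep(1, 6), rev(rep(1, 6)), type = "open")
  expect_lt(max(abs(h[1:11] - fir)), 1e-12)
  expect_true(all(abs(h[12:31]) < 1e-12))
})

test_that("high-pass filter has zero DC gain and 16-sample delay", {
  expect_equal(highpass_filter(numeric(64)), numeric(64))
  h <- highpass_filter(c(1, numeric(255)))
  expect_lt(abs(sum(h)), 1e-9)                       # DC gain 0
  step <- rep(1, 200)
  expect_lt(abs(tail(highpass_filter(step), 1)), 1e-9)
  # group delay ~ 16 samples on a narrowband tone (cross-correlation lag)
  t <- 0:3999
  x <- sin(2 * pi * 8 * t / 200)
  y <- highpass_filter(x)
  lags <- 0:40
  cc <- vapply(lags, function(l) sum(x[1:3000] * y[1:3000 + l]), numeric(1))
  expect_equal(lags[which.max(cc)], 16)
})

test_that("band-pass cascade is linear and peaks between 5 and 15 Hz", {
  set.seed(2)
  x <- rnorm(500)
  expect_lt(max(abs(bandpass_filter(3.7 * x) - 3.7 * bandpass_filter(x))), 1e-9)
  fpeak <- bandpass_peak_frequency()
  expect_gte(fpeak, 5)
  expect_lte(fpeak, 15)
})

test_that("50 Hz is attenuated at least 10x relative to 8 Hz", {
  t <- (0:3999) / 200
  rms <- function(f) {
    y <- bandpass_filter(sin(2 * pi * f * t))
    sqrt(mean(y[1000:4000]^2))
  }
  expect_gt(rms(8) / rms(50), 10)
})

test_that("derivative filter matches the five-point formula", {
  expect_error(derivative_filter(c(1, 2, 3)), "5 samples")
  expect_equal(derivative_filter(rep(2, 50), fs = 200), numeric(50))
  # ramp x(n) = n * D mV has slope exactly 1 mV/s in the interior
  fs <- 200
  x <- (0:99) / fs
  y <- derivative_filter(x, fs)
  expect_lt(max(abs(y[3:98] - 1)), 1e-12)
  # antisymmetry: centered impulse gives zero at the center
  y2 <- derivative_filter(c(0, 0, 1, 0, 0), fs = 1)
  expect_equal(y2[3], 0)
})

test_that("squaring stage is non-negative and even", {
  expect_equal(rectify_square(c(-2, 3)), c(4, 9))
  set.seed(3)
  x <- rnorm(100)
  expect_true(all(rectify_square(x) >= 0))
  expect_equal(rectify_square(x), rectify_square(-x))
})

test_that("moving-window integration equals the brute-force trailing mean", {
  expect_error(moving_window_integrate(1:5, 0), ">= 1")
  expect_equal(moving_window_integrate(rep(3, 40), 7), rep(3 * pmin(1:40, 7) / 7, 1))
  # impulse -> plateau of 1/M for M samples
  y <- moving_window_integrate(c(1, numeric(59)), 30)
  expect_equal(y[1:30], rep(1 / 30, 30))
  expect_equal(y[31:60], numeric(30))
  set.seed(4)
  x <- rnorm(1000)
  M <- 30L
  brute <- vapply(seq_along(x), function(m)
    sum(x[max(1L, m - M + 1L):m]) / M, numeric(1))
  expect_lt(max(abs(moving_window_integrate(x, M) - brute)), 1e-12)
})

test_that("resampling preserves spectral content and rescales annotations", {
  rec <- ecg_record(sin(2 * pi * 10 * (0:3599) / 360), 360, r_peaks = 360)
  expect_identical(resample_to_processing_rate(rec, 360), rec)
  out <- resample_to_processing_rate(rec, 200)
  expect_equal(out$fs, 200)
  expect_equal(out$r_peaks, 200L)
  spec <- Mod(fft(out$samples))
  n <- length(out$samples)
  fpeak <- (which.max(spec[2:(n %/% 2)])) * 200 / n
  expect_lt(abs(fpeak - 10), 0.2)
  expect_error(resample_to_processing_rate(rec, -1), "positive")
})

test_that("detector finds every beat on clean synthetic ECG", {
  for (hr in c(50, 60, 100, 140)) {
    rec <- generate_clean_ecg(synth_config(fs = 360, duration = 60,
                                           heart_rate = hr, seed = hr))
    det <- detect_r_peaks(rec)
    expect_equal(length(det$r_peaks), length(rec$r_peaks))
    m <- match_peaks(det$r_peaks, rec$r_peaks, rec$fs)
    expect_gte(m[["sensitivity"]], 0.99)
    expect_gte(m[["ppv"]], 0.99)
  }
})

test_that("flat or empty signals yield no detections, not errors", {
  expect_equal(detect_r_peaks(ecg_record(numeric(2000), 200))$r_peaks,
               integer(0))
  expect_error(detect_r_peaks(ecg_record(numeric(100), 200)), "2 s")
})

test_that("detector survives powerline interference", {
  cfg <- synth_config(fs = 360, duration = 60, heart_rate = 60, seed = 21,
                      noise_spec = list(powerline = list(amplitude = 0.3,
                                                         hz = 50)))
  rec <- generate_clean_ecg(cfg)
  m <- match_peaks(detect_r_peaks(rec)$r_peaks, rec$r_peaks, rec$fs)
  expect_gte(m[["sensitivity"]], 0.95)
})

test_that("segmentation windows are 600 ms, centered, and bounds-checked", {
  rec <- generate_clean_ecg(synth_config(fs = 360, duration = 20,
                                         heart_rate = 70, seed = 5))
  segs <- segment_beats(rec, rec$r_peaks)
  L <- round(0.600 * 360)
  expect_equal(L, 216)
  for (b in segs$beats) {
    expect_length(b$samples, L)
    expect_equal(b$r_index, L %/% 2)
  }
  expect_true(all(vapply(segs$beats, `[[`, character(1), "label") == "normal"))
  # a peak too close to the record edge is dropped and counted
  segs2 <- segment_beats(ecg_record(numeric(5000), 360), peaks = 10L)
  expect_length(segs2$beats, 0)
  expect_equal(segs2$n_dropped, 1L)
  # segment length depends only on fs
  segs3 <- segment_beats(ecg_record(rnorm(5000), 250), peaks = c(1000L, 2000L))
  expect_true(all(lengths(lapply(segs3$beats, `[[`, "samples")) == 150))
})
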