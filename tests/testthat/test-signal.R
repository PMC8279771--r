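fs <- 30

test_that("bandpass passes in-band tones and rejects out-of-band ones", {
  t <- (0:(60 * fs - 1)) / fs
  mid <- (15 * fs):(45 * fs)

  inband <- bandpass(brightness_series(sin(2 * pi * 1.33 * t), fs))
  expect_lt(abs(max(abs(inband$values[mid])) - 1), 0.05)

  slow <- bandpass(brightness_series(sin(2 * pi * 0.05 * t), fs))
  expect_lt(max(abs(slow$values[mid])), 0.1)

  # DC is fully out of band (residual is filtering roundoff on the
  # 128-unit level)
  flat <- bandpass(brightness_series(rep(128, 60 * fs), fs))
  expect_lt(max(abs(flat$values)), 1e-3)
  expect_lt(abs(mean(inband$values)), 0.01)

  expect_error(bandpass(brightness_series(rnorm(10), fps = 5)), "Nyquist")
  expect_error(bandpass(brightness_series(rnorm(5), fps = 30)), "too short")
})

test_that("bandpass is linear", {
  set.seed(7)
  x <- rnorm(600); y <- rnorm(600)
  bp <- function(v) bandpass(brightness_series(v, fs))$values
  expect_equal(bp(2 * x - 3 * y), 2 * bp(x) - 3 * bp(y), tolerance = 1e-8)
})

test_that("implemented filter gain matches the analytic Butterworth response", {
  spec <- filter_spec()
  freqs <- c(0.67, 1, 1.5, 2.5, 3.83)
  imp <- filter_gain(spec, fs, freqs)
  ana <- analytic_butter_gain(freqs, spec$low_cut, spec$high_cut,
                              spec$order, fs)^2  # squared: zero phase
  expect_equal(imp, ana, tolerance = 1e-6)
  # causal single-pass response
  causal <- filter_spec(zero_phase = FALSE)
  expect_equal(filter_gain(causal, fs, freqs),
               analytic_butter_gain(freqs, 0.67, 3.83, 2, fs),
               tolerance = 1e-6)
})

test_that("filtering a sinusoid at a cutoff reproduces the designed gain", {
  for (f in c(0.67, 3.83)) {
    t <- (0:(120 * fs - 1)) / fs
    y <- bandpass(brightness_series(sin(2 * pi * f * t), fs))$values
    mid <- (30 * fs):(90 * fs)
    tt <- t[mid]
    fit <- stats::lm(y[mid] ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt) - 1)
    amp <- sqrt(sum(stats::coef(fit)^2))
    expect_lt(abs(amp / 0.5 - 1), 0.01)  # |H|^2 = 1/2 at a cutoff
  }
})

test_that("second_difference matches the discrete operator", {
  quad <- brightness_series((0:20)^2, fs)
  d2 <- second_difference(quad)
  expect_equal(d2$values, rep(2, 19))
  expect_length(d2$values, 19)
  expect_equal(attr(d2, "frame_offset"), 1L)
  expect_equal(d2$start_time, 1 / fs)

  lin <- brightness_series(5 * (0:20) + 3, fs)
  expect_equal(second_difference(lin)$values, rep(0, 19))

  # unit sinusoid: amplitude -2 (1 - cos w), sign-inverted
  w <- 2 * pi * 1.2 / fs
  x <- sin(w * (0:599))
  got <- second_difference(brightness_series(x, fs))$values
  expect_equal(got, -2 * (1 - cos(w)) * x[2:599], tolerance = 1e-9)

  expect_error(second_difference(brightness_series(c(1, 2), fs)), "at least 3")
})

test_that("detect_peaks finds one peak per beat on a clean pulse train", {
  s <- synth_ppg(60, 30, pulse = pulse_model(hrv_sd = 0),
                 noise = noise_model(white_sd = 0, drift_amplitude = 0,
                                     spike_rate = 0), seed = 1)
  d2 <- second_difference(bandpass(s$series))
  pt <- detect_peaks(d2)
  expect_gte(length(pt$indices), 29)
  expect_lte(length(pt$indices), 31)
  gaps <- diff(pt$indices)
  inner <- gaps[2:(length(gaps) - 1)]  # edge cycles are filter-affected
  expect_true(all(abs(inner - 30) <= 1))
})

test_that("detect_peaks enforces prominence and distance rules", {
  expect_length(detect_peaks(brightness_series(rep(3, 100), fs))$indices, 0)

  # two candidate maxima 3 frames apart: only the more prominent survives
  x <- rep(0, 100)
  x[48:52] <- c(0.5, 1.5, 2.0, 1.5, 0.5)
  x[53] <- 1.0
  s <- brightness_series(x, fs)
  pt <- detect_peaks(s, peak_params(min_distance = 8, min_prominence = 0.5))
  expect_equal(pt$indices, 50L)

  # min-distance property on a noisy trace
  set.seed(11)
  noisy <- brightness_series(rnorm(3000), fs)
  pp <- peak_params(min_distance = 9, min_prominence = 0.5)
  got <- detect_peaks(noisy, pp)
  expect_true(all(diff(got$indices) >= 9))
})

test_that("detect_peaks agrees with an independent findpeaks on plain maxima", {
  skip_if_not_installed("pracma")
  t <- (0:299) / fs
  x <- sin(2 * pi * 1.5 * t)
  ours <- detect_peaks(brightness_series(x, fs),
                       peak_params(min_distance = 1, min_prominence = 0.5))
  ref <- pracma::findpeaks(x, minpeakheight = 0.5)
  expect_equal(ours$indices, sort(ref[, 2]))
})

test_that("peaks_to_ppi differences peak indices", {
  pt <- structure(list(indices = c(10L, 40L, 70L), fps = fs),
                  class = "peak_train")
  expect_equal(peaks_to_ppi(pt)$intervals, c(30, 30))
  pt2 <- structure(list(indices = c(0L, 22L, 45L, 90L), fps = fs),
                   class = "peak_train")
  expect_equal(peaks_to_ppi(pt2)$intervals, c(22, 23, 45))
  one <- structure(list(indices = 5L, fps = fs), class = "peak_train")
  expect_error(peaks_to_ppi(one), "insufficient peaks")

  # cumulative sum reconstructs the peak offsets exactly
  set.seed(3)
  idx <- cumsum(sample(8:40, 25, replace = TRUE))
  pt3 <- structure(list(indices = idx, fps = fs), class = "peak_train")
  expect_identical(idx[1] + cumsum(peaks_to_ppi(pt3)$intervals),
                   as.numeric(idx[-1]))
})
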