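test_that("generate_beat_times spaces beats by 60/HR over [0, duration)", {
  p60 <- pulse_model(base_hr = 60, hrv_sd = 0)
  expect_equal(generate_beat_times(p60, 10), 0:9)

  p80 <- pulse_model(base_hr = 80, hrv_sd = 0)
  beats <- generate_beat_times(p80, 60)
  expect_equal(diff(beats), rep(0.75, 79))
  expect_length(beats, 80)
  expect_lt(max(beats), 60)

  jit <- pulse_model(base_hr = 70, hrv_sd = 4)
  b1 <- generate_beat_times(jit, 120, seed = 8)
  b2 <- generate_beat_times(jit, 120, seed = 8)
  expect_identical(b1, b2)
  expect_true(all(diff(b1) > 0))
})

test_that("rendered signals put their spectral peak at the pulse rate", {
  nz0 <- noise_model(white_sd = 0, drift_amplitude = 0, spike_rate = 0)
  for (hr in c(55, 72, 96)) {
    p <- pulse_model(base_hr = hr, hrv_sd = 0)
    s <- render_brightness(generate_beat_times(p, 60), p, nz0,
                           fps = 30, duration = 60)
    v <- s$values - mean(s$values)
    spec <- Mod(stats::fft(v))[2:(length(v) / 2)]
    f <- (seq_along(spec)) / 60  # bin width 1/60 Hz
    expect_lt(abs(f[which.max(spec)] - hr / 60), 1 / 60 + 1e-9)
  }
})

test_that("render_brightness degenerates to baseline without a pulse", {
  p <- pulse_model(base_hr = 60, hrv_sd = 0, amplitude = 0)
  nz0 <- noise_model(white_sd = 0, drift_amplitude = 0, spike_rate = 0)
  s <- render_brightness(generate_beat_times(p, 10), p, nz0, duration = 10)
  expect_equal(s$values, rep(p$baseline_level, 300))
})

test_that("inject_artifacts is an identity at zero rates and deterministic", {
  beats <- generate_beat_times(pulse_model(hrv_sd = 0), 60)
  none <- inject_artifacts(beats, artifact_model(0, 0), seed = 1)
  expect_equal(none$times, beats)
  expect_equal(none$amps, rep(1, length(beats)))
  expect_equal(nrow(none$events), 0)

  a <- inject_artifacts(beats, artifact_model(0.15, 0.1), seed = 2)
  b <- inject_artifacts(beats, artifact_model(0.15, 0.1), seed = 2)
  expect_identical(a, b)
  expect_true(all(a$events$type %in% c("missed", "bump")))
  expect_equal(sum(a$amps < 0.05), sum(a$events$type == "missed"))
})

test_that("every injected artifact maps to an interval-level deviation", {
  p <- pulse_model(base_hr = 80, hrv_sd = 0)
  nz0 <- noise_model(white_sd = 0, drift_amplitude = 0, spike_rate = 0)
  beats <- generate_beat_times(p, 90)

  # events within a couple of seconds of the recording edges may fall
  # outside the detectable span; interior events must all register
  interior <- function(ev, type) sum(ev$type == type & ev$time > 2 & ev$time < 88)

  sched_m <- inject_artifacts(beats, artifact_model(0.1, 0), seed = 3)
  s <- render_brightness(sched_m, p, nz0, duration = 90)
  ppi <- peaks_to_ppi(detect_peaks(second_difference(bandpass(s))))
  med <- stats::median(ppi$intervals)
  n_long <- sum(ppi$intervals > 1.7 * med)
  expect_gte(n_long, interior(sched_m$events, "missed"))
  expect_lte(n_long, sum(sched_m$events$type == "missed"))

  sched_b <- inject_artifacts(beats, artifact_model(0, 0.15), seed = 4)
  s2 <- render_brightness(sched_b, p, nz0, duration = 90)
  ppi2 <- peaks_to_ppi(detect_peaks(second_difference(bandpass(s2))))
  med2 <- stats::median(ppi2$intervals)
  n_short <- sum(ppi2$intervals < 0.7 * med2)
  expect_gte(n_short, 2 * interior(sched_b$events, "bump"))
  expect_lte(n_short, 2 * sum(sched_b$events$type == "bump"))
})

test_that("render_video round-trips through extract_brightness", {
  s <- brightness_series(128 + sin(2 * pi * (0:9) / 10), fps = 30)
  vid <- render_video(s, frame_shape = c(8, 8))
  expect_equal(extract_brightness(vid)$values, s$values, tolerance = 1e-12)

  # pixel noise sd 5 on 100x100 frames: frame-mean error sd ~ 5/100
  s2 <- brightness_series(rep(128, 200), fps = 30)
  vid2 <- render_video(s2, frame_shape = c(100, 100), pixel_noise_sd = 5,
                       seed = 6)
  err <- extract_brightness(vid2)$values - s2$values
  expect_gt(stats::sd(err), 0.03)
  expect_lt(stats::sd(err), 0.07)

  expect_error(render_video(s, frame_shape = c(0, 10)), "positive")
})

test_that("generate_cohort is reproducible and honours the null", {
  spec <- cohort_spec(n_per_group = 2, n_stimuli = 2, stimulus_duration = 60,
                      seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$participants[[1]]$trial_series$values,
                   c2$participants[[1]]$trial_series$values)

  null_spec <- cohort_spec(n_per_group = 30, n_stimuli = 1,
                           stimulus_duration = 20, trial_duration = 5,
                           group_effect_p2 = 0, seed = 7)
  nc <- generate_cohort(null_spec)
  expect_lt(abs(mean(nc$truth$log_ratio_p2)), 0.01)
  expect_equal(sort(unique(nc$truth$condition)), c("control", "tracing"))
})

test_that("cohort manifests round-trip through disk", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_per_group = 1, n_stimuli = 2, stimulus_duration = 20,
                      trial_duration = 10, seed = 5)
  coh <- generate_cohort(spec, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort_manifest(file.path(dir, "manifest.json"))
  expect_length(back$participants, 2)
  expect_equal(back$participants[[1]]$trial_series$values,
               coh$participants[[1]]$trial_series$values, tolerance = 1e-9)
  expect_equal(back$participants[[2]]$condition, "control")
})
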