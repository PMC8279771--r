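test_that("estimate_period_hr recovers the rate of a clean recording", {
  s <- synth_ppg(80, 90, noise = quiet_noise(), seed = 301)
  est <- estimate_period_hr(s$series, c(10, 70))
  expect_lt(abs(est$h - 80), 1)

  expect_error(estimate_period_hr(brightness_series(rep(128, 900), 30)),
               "insufficient|peaks")

  s60 <- synth_ppg(60, 90, noise = quiet_noise(), seed = 302)
  est60 <- estimate_period_hr(s60$series, c(5, 90))
  expect_gte(est60$n_ppi, 80)
  expect_lte(est60$n_ppi, 88)
})

test_that("change_ratios computes baseline-normalised log ratios", {
  cr <- change_ratios(80, 80, 80 * exp(-0.05))
  expect_equal(cr$log_ratio_p1, 0)
  expect_equal(cr$log_ratio_p2, -0.05)
  # antisymmetric under exchanging baseline and period rates
  expect_equal(change_ratios(76, 80, 80)$log_ratio_p1,
               -change_ratios(80, 76, 76)$log_ratio_p1)
  expect_error(change_ratios(-1, 80, 80), "positive")
})

make_participant <- function(hr_b, p2_rates, seed, p1_rate = hr_b,
                             noise = quiet_noise(), ...) {
  set.seed(seed)
  trial <- synth_ppg(hr_b, 30, noise = noise)$series
  stim <- lapply(p2_rates, function(r2) {
    synth_ppg(p1_rate, 180, noise = noise,
              hr_fn = function(t) if (t < 90) p1_rate else r2)$series
  })
  participant_change_ratios(trial, stim, ...)
}

test_that("participant log ratios track per-period rates", {
  # all periods at the same rate: ratios near zero
  rec <- make_participant(80, rep(80, 2), seed = 310)
  expect_lt(abs(rec$log_ratio_p1), 0.01)
  expect_lt(abs(rec$log_ratio_p2), 0.01)

  # four stimuli with second-period rates 76-82 around an 80 baseline
  rec2 <- make_participant(80, c(76, 78, 80, 82), seed = 311)
  expect_lt(abs(rec2$log_ratio_p2 - log(79 / 80)), 0.01)
  expect_false(rec2$qc$excluded)
})

test_that("pooled-interval aggregation agrees with per-stimulus averaging", {
  rec_a <- make_participant(72, rep(72, 3), seed = 312, aggregate = "average")
  rec_p <- make_participant(72, rep(72, 3), seed = 312, aggregate = "pooled")
  expect_lt(abs(rec_a$h_p2 - rec_p$h_p2), 1)
})

test_that("heart rates and ratios are invariant to brightness scale", {
  set.seed(313)
  trial <- synth_ppg(75, 30, noise = quiet_noise())$series
  stim <- synth_ppg(75, 180, noise = quiet_noise())$series
  rec1 <- participant_change_ratios(trial, list(stim))
  scale_bs <- function(s, c) brightness_series(c * s$values, s$fps, s$start_time)
  rec2 <- participant_change_ratios(scale_bs(trial, 3.7), list(scale_bs(stim, 3.7)))
  expect_equal(rec2$h_b, rec1$h_b, tolerance = 1e-6)
  expect_equal(rec2$log_ratio_p2, rec1$log_ratio_p2, tolerance = 1e-6)
})

test_that("QC flags boundary hits, noise-only input and estimation failures", {
  # a clean participant passes the default thresholds (asserted above);
  # force a boundary-hit record via a constructed estimate
  fake_est <- function(boundary = FALSE, loss = 10, n = 60) {
    structure(list(m_prime = 22.5, loss = loss, h = 80, fps = 30, n_ppi = n,
                   scale_assignment_counts = c("2" = 0, "1" = n, "0.5" = 0),
                   tie_detected = FALSE, alias_corrected = FALSE,
                   boundary_hit = boundary), class = "hr_estimate")
  }
  rec <- structure(list(id = "x", condition = "control",
                        frequency_of_viewing = 0, h_b = 80, h_p1 = 80,
                        h_p2 = 80, log_ratio_p1 = 0, log_ratio_p2 = 0,
                        estimates = list(baseline = fake_est(),
                                         p1 = list(fake_est(boundary = TRUE)),
                                         p2 = list(fake_est(boundary = TRUE))),
                        failures = character(0), qc = NULL),
                   class = "participant_record")
  qc <- apply_qc(rec)
  expect_true(qc$excluded)
  expect_true(any(grepl("boundary-hit", qc$reasons)))

  # pure-noise brightness input is excluded with a reason
  set.seed(314)
  noise_trial <- brightness_series(rnorm(900, 128, 1), 30)
  noise_stim <- brightness_series(rnorm(5400, 128, 1), 30)
  rec_n <- participant_change_ratios(noise_trial, list(noise_stim))
  expect_true(rec_n$qc$excluded)
  expect_gt(length(rec_n$qc$reasons), 0)
})

test_that("exclusions grow monotonically as QC thresholds tighten", {
  set.seed(315)
  coh <- generate_cohort(cohort_spec(n_per_group = 6, seed = 99))
  recs <- run_study(coh)
  loose <- vapply(recs, function(r) apply_qc(r, qc_config())$excluded,
                  logical(1))
  strict <- vapply(recs, function(r) {
    apply_qc(r, qc_config(min_ppi = 60, max_loss_per_interval = 1))$excluded
  }, logical(1))
  expect_true(all(strict[loose]))  # excluded set only grows
})

test_that("summarize_cohort stratifies by condition and viewing frequency", {
  fake_rec <- function(id, cond, freq, lr2 = -0.05, excluded = FALSE) {
    structure(list(id = id, condition = cond, frequency_of_viewing = freq,
                   h_b = 80, h_p1 = 80, h_p2 = 80 * exp(lr2),
                   log_ratio_p1 = 0, log_ratio_p2 = lr2,
                   estimates = list(baseline = NULL, p1 = list(), p2 = list()),
                   failures = character(0),
                   qc = structure(list(excluded = excluded,
                                       reasons = if (excluded) "x" else character(0)),
                                  class = "qc_report")),
              class = "participant_record")
  }
  recs <- list(fake_rec("a", "tracing", 0), fake_rec("b", "tracing", 2),
               fake_rec("c", "control", 0), fake_rec("d", "control", 0),
               fake_rec("e", "control", 1, excluded = TRUE))
  sm <- summarize_cohort(recs)
  expect_equal(nrow(sm), 4)
  low_t <- sm[sm$condition == "tracing" & sm$frequency_group == "low", ]
  expect_equal(low_t$n, 1)
  expect_equal(low_t$log_ratio_p2_mean, -0.05)
  expect_true(is.na(low_t$log_ratio_p2_sd))  # singleton stratum
  high_c <- sm[sm$condition == "control" & sm$frequency_group == "high", ]
  expect_equal(high_c$n, 0)
  expect_equal(high_c$n_excluded, 1)

  all_ex <- list(fake_rec("a", "tracing", 0, excluded = TRUE))
  expect_error(summarize_cohort(all_ex), "all participants excluded")
})
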