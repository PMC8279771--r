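# Synthetic fingertip-PPG generator: pulse trains, brightness traces,
# detection artifacts, frame stacks and two-condition cohorts with known
# ground truth, so every pipeline stage is testable without recordings.

# internal: run code under a temporary RNG state seeded with `seed`;
# NULL seed leaves the current RNG stream untouched (used when a caller
# has already seeded an enclosing simulation).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Pulse waveform model
#'
#' Describes the periodic blood-volume pulse placed at each beat. Each
#' cycle carries a raised-cosine absorption dip,
#' `w(phi) = -sum_j harmonics[j] * (1 - cos(2 pi j phi))`: at systole the
#' extra blood absorbs light, so fingertip brightness dips once per beat.
#' The shape is continuously differentiable with zero slope at the cycle
#' boundaries, so per-beat amplitude changes (attenuated or spurious
#' pulses) introduce no spurious curvature of their own, and its
#' second-derivative maximum lies at the dip centre — one detection per
#' beat. The default second-harmonic amplitude (0.05) keeps the curvature
#' trace single-peaked per beat: double differentiation amplifies the
#' j-th harmonic j^2-fold, and second harmonics above ~1/16 create a
#' second detectable curvature maximum every cycle — systematic double
#' counting that no averaging scheme can undo.
#'
#' @param base_hr mean heart rate in beats per minute (default 70).
#' @param hrv_sd beat-to-beat heart-rate jitter, SD in bpm (default 3).
#' @param harmonics amplitudes of the harmonic components of the pulse
#'   shape (default `c(1, 0.05)`).
#' @param amplitude pulse amplitude in brightness units (default 1).
#' @param baseline_level constant brightness offset (default 128, the
#'   midpoint of an 8-bit channel).
#' @return an object of class `pulse_model`.
#' @export
pulse_model <- function(base_hr = 70, hrv_sd = 3, harmonics = c(1, 0.05),
                        amplitude = 1, baseline_level = 128) {
  if (base_hr <= 0) stop("`base_hr` must be positive", call. = FALSE)
  if (hrv_sd < 0 || amplitude < 0) {
    stop("`hrv_sd` and `amplitude` must be non-negative", call. = FALSE)
  }
  structure(
    list(base_hr = base_hr, hrv_sd = hrv_sd, harmonics = harmonics,
         amplitude = amplitude, baseline_level = baseline_level),
    class = "pulse_model"
  )
}

#' Additive noise model for synthetic brightness traces
#'
#' White sensor noise is small because the trace is a whole-frame mean
#' (spatial averaging over ~10^5 pixels); the dominant disturbances in real
#' recordings are slow drift (finger pressure, exposure; respiration-like
#' default 0.25 Hz, below the pass band) and sporadic motion transients.
#' Motion artifacts span several frames (a finger shift takes a few tenths
#' of a second), so spikes are rendered as Gaussian-shaped transients of
#' width `spike_width` rather than single-frame deltas, which would have a
#' physically implausible flat spectrum.
#'
#' @param white_sd white-noise SD, brightness units (default 0.02).
#' @param drift_amplitude sinusoidal drift amplitude (default 2).
#' @param drift_freq drift frequency in Hz (default 0.25).
#' @param spike_rate motion transients per minute (default 0.25).
#' @param spike_amplitude transient peak height, brightness units
#'   (default 3).
#' @param spike_width transient SD in seconds (default 0.15).
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(white_sd = 0.02, drift_amplitude = 2,
                        drift_freq = 0.25, spike_rate = 0.25,
                        spike_amplitude = 3, spike_width = 0.15) {
  vals <- c(white_sd, drift_amplitude, drift_freq, spike_rate,
            spike_amplitude, spike_width)
  if (any(vals < 0)) stop("noise parameters must be non-negative", call. = FALSE)
  structure(
    list(white_sd = white_sd, drift_amplitude = drift_amplitude,
         drift_freq = drift_freq, spike_rate = spike_rate,
         spike_amplitude = spike_amplitude, spike_width = spike_width),
    class = "noise_model"
  )
}

#' Detection-artifact model
#'
#' Emulates the two failure modes of PPG beat detection: a fraction of
#' beats whose pulse is attenuated to near zero (the detector skips them,
#' doubling an interval) and a fraction of inter-beat gaps receiving a
#' spurious mid-cycle bump (the detector counts two peaks in one cycle,
#' halving an interval).
#'
#' @param missed_pulse_rate fraction of beats attenuated, in `[0, 1)`.
#' @param extra_bump_rate fraction of gaps receiving a spurious bump,
#'   in `[0, 1)`.
#' @return an object of class `artifact_model`.
#' @export
artifact_model <- function(missed_pulse_rate = 0, extra_bump_rate = 0) {
  if (missed_pulse_rate < 0 || missed_pulse_rate >= 1 ||
      extra_bump_rate < 0 || extra_bump_rate >= 1) {
    stop("artifact rates must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(missed_pulse_rate = missed_pulse_rate,
         extra_bump_rate = extra_bump_rate),
    class = "artifact_model"
  )
}

#' Generate beat times with beat-to-beat variability
#'
#' Beats start at time 0; each gap is `60 / hr` seconds where `hr` is
#' `base_hr` (or `hr_fn(t)`) plus independent Gaussian jitter of SD
#' `hrv_sd`, floored at 20 bpm. Beats cover the half-open interval
#' `[0, duration)`.
#'
#' @param model a [pulse_model()].
#' @param duration recording length in seconds.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param hr_fn optional function of time (seconds) returning the
#'   instantaneous mean heart rate, overriding `base_hr`; used for
#'   two-level stimulus recordings.
#' @return strictly increasing numeric vector of beat times in seconds.
#' @export
generate_beat_times <- function(model, duration, seed = NULL, hr_fn = NULL) {
  stopifnot(inherits(model, "pulse_model"))
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  with_seed(seed, {
    times <- numeric(0)
    t <- 0
    while (t < duration) {
      times <- c(times, t)
      hr <- if (is.null(hr_fn)) model$base_hr else hr_fn(t)
      if (model$hrv_sd > 0) hr <- hr + stats::rnorm(1, 0, model$hrv_sd)
      hr <- max(hr, 20)
      t <- t + 60 / hr
    }
    times
  })
}

# internal: the periodic pulse waveform on phase in [0, 1); a negative
# raised-cosine dip, C^1 at the cycle boundaries
pulse_waveform <- function(phase, harmonics) {
  w <- rep(0, length(phase))
  for (j in seq_along(harmonics)) {
    w <- w - harmonics[j] * (1 - cos(2 * pi * j * phase))
  }
  w
}

# internal: normalise a beat-times vector or schedule list to a schedule
as_beat_schedule <- function(beats) {
  empty_bumps <- data.frame(time = numeric(0), amp = numeric(0),
                            width = numeric(0))
  if (is.numeric(beats)) {
    list(times = beats, amps = rep(1, length(beats)), bumps = empty_bumps,
         events = data.frame(type = character(0), time = numeric(0)))
  } else if (is.list(beats) && all(c("times", "amps") %in% names(beats))) {
    if (is.null(beats$events)) {
      beats$events <- data.frame(type = character(0), time = numeric(0))
    }
    if (is.null(beats$bumps)) beats$bumps <- empty_bumps
    beats
  } else {
    stop("`beats` must be a numeric vector or a beat schedule", call. = FALSE)
  }
}

#' Inject missed-pulse and extra-bump artifacts into a beat schedule
#'
#' Attenuates randomly chosen beats to near-zero amplitude (the cycle's
#' curvature peak falls far below the detector's prominence threshold, so
#' the beat is skipped and the interval doubles) and plants
#' reduced-amplitude spurious dips midway between the genuine detection
#' points of randomly chosen gaps (detected as extra peaks, splitting an
#' interval into halves). Returns the modified schedule together with a
#' ground-truth event log for assertions.
#'
#' @param beats numeric vector of beat times or a beat schedule.
#' @param model an [artifact_model()].
#' @param seed optional integer seed.
#' @return a beat schedule: list with `times`, `amps` (per-beat amplitude
#'   multipliers) and `events` (data frame of `type` in
#'   `"missed"`/`"bump"` and `time`).
#' @export
inject_artifacts <- function(beats, model = artifact_model(), seed = NULL) {
  stopifnot(inherits(model, "artifact_model"))
  sched <- as_beat_schedule(beats)
  with_seed(seed, {
    n <- length(sched$times)
    events <- sched$events
    if (model$missed_pulse_rate > 0 && n > 2) {
      # sporadic single-beat failures at the nominal rate, kept at least
      # two live beats apart: closer misses would merge three or more
      # cycles into one interval, which the harmonic scale set cannot
      # represent (a double-length interval is the modelled failure)
      n_miss <- round(model$missed_pulse_rate * n)
      hit <- rep(FALSE, n)
      eligible <- setdiff(seq_len(n), c(1L, n))
      while (n_miss > 0L && length(eligible) > 0L) {
        pick <- eligible[sample.int(length(eligible), 1L)]
        hit[pick] <- TRUE
        eligible <- setdiff(eligible, (pick - 2L):(pick + 2L))
        n_miss <- n_miss - 1L
      }
      if (any(hit)) {
        sched$amps[hit] <- sched$amps[hit] * 0.02
        events <- rbind(events, data.frame(type = "missed",
                                           time = sched$times[hit]))
      }
    }
    if (model$extra_bump_rate > 0 && n > 2) {
      # detection points sit at cycle centres; a spurious dip lands midway
      # between two consecutive centres so both resulting intervals are
      # half-length (the classic double-counting signature)
      centres <- (sched$times[-n] + sched$times[-1]) / 2
      n_c <- length(centres)
      pickable <- seq_len(n_c - 1L)
      chosen <- pickable[stats::runif(n_c - 1L) < model$extra_bump_rate]
      if (length(chosen)) {
        mid <- (centres[chosen] + centres[chosen + 1L]) / 2
        width <- (centres[chosen + 1L] - centres[chosen]) / 2
        sched$bumps <- rbind(sched$bumps,
                             data.frame(time = mid, amp = 1, width = width))
        events <- rbind(events, data.frame(type = "bump", time = mid))
      }
    }
    sched$events <- events[order(events$time), , drop = FALSE]
    sched
  })
}

#' Render a brightness trace from a beat schedule
#'
#' Sums a baseline level, one pulse waveform per beat (harmonic synthesis
#' with per-beat amplitude, phase-locked to the beat-to-beat gaps),
#' sinusoidal drift, white noise and sporadic single-frame spikes, sampled
#' at `fps`.
#'
#' @param beats numeric vector of beat times or a beat schedule (e.g. from
#'   [inject_artifacts()]).
#' @param pulse a [pulse_model()].
#' @param noise a [noise_model()].
#' @param fps sampling rate in frames/second (default 30).
#' @param duration trace length in seconds; defaults to the span of the
#'   beat times plus one nominal gap.
#' @param seed optional integer seed (noise and spikes).
#' @return a [brightness_series()].
#' @export
render_brightness <- function(beats, pulse = pulse_model(),
                              noise = noise_model(), fps = 30,
                              duration = NULL, seed = NULL) {
  stopifnot(inherits(pulse, "pulse_model"), inherits(noise, "noise_model"))
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  sched <- as_beat_schedule(beats)
  times <- sched$times
  amps <- sched$amps
  if (length(times) < 1L) stop("need at least one beat", call. = FALSE)
  gap0 <- if (length(times) >= 2L) stats::median(diff(times)) else 60 / pulse$base_hr
  if (is.null(duration)) duration <- max(times) + gap0
  n <- as.integer(round(duration * fps))
  t <- (0:(n - 1)) / fps

  # pad the schedule so every sample falls inside a defined cycle
  while (times[1] > 0) {
    times <- c(times[1] - gap0, times)
    amps <- c(1, amps)
  }
  while (times[length(times)] <= duration) {
    times <- c(times, times[length(times)] + gap0)
    amps <- c(amps, 1)
  }

  k <- findInterval(t, times)
  phase <- (t - times[k]) / (times[k + 1] - times[k])
  wave <- pulse_waveform(phase, pulse$harmonics)
  # the waveform and its slope vanish at cycle boundaries, so constant
  # per-cycle amplitudes join without kinks
  vals <- pulse$baseline_level + pulse$amplitude * amps[k] * wave
  if (nrow(sched$bumps)) {
    for (b in seq_len(nrow(sched$bumps))) {
      tb <- sched$bumps$time[b]; wd <- sched$bumps$width[b]
      u <- (t - tb) / (wd / 2)
      inside <- abs(u) <= 1
      vals[inside] <- vals[inside] - pulse$amplitude * sched$bumps$amp[b] *
        (1 + cos(pi * u[inside])) / 2
    }
  }

  with_seed(seed, {
    if (noise$drift_amplitude > 0) {
      vals <- vals + noise$drift_amplitude * sin(2 * pi * noise$drift_freq * t)
    }
    if (noise$white_sd > 0) vals <- vals + stats::rnorm(n, 0, noise$white_sd)
    if (noise$spike_rate > 0 && noise$spike_amplitude > 0) {
      m <- stats::rpois(1, noise$spike_rate * duration / 60)
      if (m > 0) {
        centers <- stats::runif(m, 0, duration)
        signs <- sample(c(-1, 1), m, replace = TRUE)
        width <- max(noise$spike_width, 1 / fps)
        for (s in seq_len(m)) {
          vals <- vals + signs[s] * noise$spike_amplitude *
            exp(-(t - centers[s])^2 / (2 * width^2))
        }
      }
    }
    brightness_series(vals, fps)
  })
}

#' Convenience generator: one synthetic PPG recording
#'
#' Composes [generate_beat_times()], [inject_artifacts()] and
#' [render_brightness()] under a single seed.
#'
#' @param base_hr mean heart rate in bpm.
#' @param duration recording length in seconds.
#' @param fps frames per second (default 30).
#' @param pulse a [pulse_model()]; its `base_hr` is overridden.
#' @param noise a [noise_model()].
#' @param artifacts an [artifact_model()].
#' @param seed optional integer seed.
#' @param hr_fn optional instantaneous-rate function passed to
#'   [generate_beat_times()].
#' @return list with `series` (a [brightness_series()]), `schedule` (the
#'   beat schedule incl. the artifact event log) and `beat_times`.
#' @export
synth_ppg <- function(base_hr, duration, fps = 30, pulse = pulse_model(),
                      noise = noise_model(), artifacts = artifact_model(),
                      seed = NULL, hr_fn = NULL) {
  pulse$base_hr <- base_hr
  with_seed(seed, {
    bt <- generate_beat_times(pulse, duration, hr_fn = hr_fn)
    sched <- inject_artifacts(bt, artifacts)
    series <- render_brightness(sched, pulse, noise, fps = fps,
                                duration = duration)
    list(series = series, schedule = sched, beat_times = bt)
  })
}

#' Render a frame stack whose red channel carries a brightness series
#'
#' Produces a [raw_video()] whose per-frame red-channel mean equals the
#' series value up to i.i.d. pixel noise, so [extract_brightness()] can be
#' exercised round-trip. Green and blue channels carry scaled copies.
#'
#' @param series a [brightness_series()].
#' @param frame_shape integer vector `c(height, width)` (default 20 x 20).
#' @param pixel_noise_sd SD of per-pixel noise on the red channel
#'   (default 0).
#' @param seed optional integer seed.
#' @return a [raw_video()].
#' @export
render_video <- function(series, frame_shape = c(20, 20), pixel_noise_sd = 0,
                         seed = NULL) {
  stopifnot(inherits(series, "brightness_series"))
  h <- frame_shape[1]; w <- frame_shape[2]
  if (length(frame_shape) != 2L || h < 1 || w < 1) {
    stop("`frame_shape` must be two positive dimensions", call. = FALSE)
  }
  n <- length(series$values)
  with_seed(seed, {
    frames <- array(0, dim = c(h, w, 3, n))
    for (i in seq_len(n)) {
      v <- series$values[i]
      red <- matrix(v, h, w)
      if (pixel_noise_sd > 0) {
        red <- red + matrix(stats::rnorm(h * w, 0, pixel_noise_sd), h, w)
      }
      frames[, , 1, i] <- red
      frames[, , 2, i] <- 0.5 * v
      frames[, , 3, i] <- 0.3 * v
    }
    raw_video(frames, series$fps)
  })
}

#' Two-condition cohort specification
#'
#' Ground-truth generative parameters for a simulated study: per-group
#' sample sizes, the baseline heart-rate distribution, and the true mean
#' shift of `ln(h_p2 / h_b)` applied to the tracing group during the second
#' half of each stimulus.
#'
#' @param n_per_group participants per condition; scalar or named vector
#'   `c(tracing = ..., control = ...)` (default 30 each).
#' @param baseline_hr_mean cohort mean baseline heart rate, bpm
#'   (default 80).
#' @param baseline_hr_sd between-participant SD, bpm (default 8).
#' @param group_effect_p2 true mean shift of the second-period log change
#'   ratio in the tracing group (default -0.05; control group is 0).
#' @param within_subject_sd SD of per-participant deviations of the period
#'   log ratios around their true means (default 0.02).
#' @param trial_duration baseline (trial) recording length, s (default 30).
#' @param stimulus_duration stimulus recording length, s (default 180).
#' @param n_stimuli stimulus recordings per participant (default 4).
#' @param fps frames per second (default 30).
#' @param seed integer seed; a fixed seed yields identical cohorts.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 30, baseline_hr_mean = 80,
                        baseline_hr_sd = 8, group_effect_p2 = -0.05,
                        within_subject_sd = 0.02, trial_duration = 30,
                        stimulus_duration = 180, n_stimuli = 4, fps = 30,
                        seed = 1) {
  if (length(n_per_group) == 1L) {
    n_per_group <- c(tracing = n_per_group, control = n_per_group)
  }
  if (!all(c("tracing", "control") %in% names(n_per_group))) {
    stop("`n_per_group` must name tracing and control counts", call. = FALSE)
  }
  if (any(n_per_group < 1)) stop("need at least one participant per group", call. = FALSE)
  structure(
    list(n_per_group = n_per_group, baseline_hr_mean = baseline_hr_mean,
         baseline_hr_sd = baseline_hr_sd, group_effect_p2 = group_effect_p2,
         within_subject_sd = within_subject_sd,
         trial_duration = trial_duration,
         stimulus_duration = stimulus_duration, n_stimuli = n_stimuli,
         fps = fps, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic two-condition cohort with known ground truth
#'
#' For each participant: a baseline heart rate drawn from the cohort
#' distribution (truncated to 50-115 bpm so the interval grid identifies
#' it), one trial recording at that rate, and `n_stimuli` stimulus
#' recordings whose first half runs at the participant's first-period rate
#' and whose second half embodies the group effect on `ln(h_p2 / h_b)`.
#' Frequency-of-viewing scores are drawn skewed toward 0, mirroring a
#' population that rarely views calligraphy.
#'
#' @param spec a [cohort_spec()].
#' @param pulse a [pulse_model()] (per-participant `base_hr` is set
#'   internally).
#' @param noise a [noise_model()].
#' @param artifacts an [artifact_model()]; default 5% missed pulses and 5%
#'   extra bumps, the sporadic detection failures typical of smartphone
#'   recordings.
#' @param out_dir optional directory; when given, brightness CSVs, a
#'   `manifest.json` and a `truth.csv` are written there.
#' @return list with `participants` (each: `id`, `condition`,
#'   `frequency_of_viewing`, `trial_series`, `stimulus_series` (list),
#'   `truth`) and `truth` (data frame of true rates and log ratios).
#' @export
generate_cohort <- function(spec = cohort_spec(), pulse = pulse_model(),
                            noise = noise_model(),
                            artifacts = artifact_model(0.05, 0.05),
                            out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    participants <- list()
    truth_rows <- list()
    pid <- 0L
    for (grp in c("tracing", "control")) {
      effect <- if (grp == "tracing") spec$group_effect_p2 else 0
      for (i in seq_len(spec$n_per_group[[grp]])) {
        pid <- pid + 1L
        id <- sprintf("P%03d", pid)
        repeat {
          hr_b <- stats::rnorm(1, spec$baseline_hr_mean, spec$baseline_hr_sd)
          if (hr_b >= 50 && hr_b <= 115) break
        }
        hr_p1 <- hr_b * exp(stats::rnorm(1, 0, spec$within_subject_sd))
        hr_p2 <- hr_b * exp(effect + stats::rnorm(1, 0, spec$within_subject_sd))
        freq <- sample(0:3, 1, prob = c(0.65, 0.2, 0.1, 0.05))

        trial <- synth_ppg(hr_b, spec$trial_duration, fps = spec$fps,
                           pulse = pulse, noise = noise,
                           artifacts = artifacts)
        half <- spec$stimulus_duration / 2
        hr_fn <- local({
          p1 <- hr_p1; p2 <- hr_p2; hh <- half
          function(t) if (t < hh) p1 else p2
        })
        stim <- lapply(seq_len(spec$n_stimuli), function(j) {
          synth_ppg(hr_p1, spec$stimulus_duration, fps = spec$fps,
                    pulse = pulse, noise = noise, artifacts = artifacts,
                    hr_fn = hr_fn)$series
        })
        participants[[pid]] <- list(
          id = id, condition = grp, frequency_of_viewing = freq,
          trial_series = trial$series, stimulus_series = stim,
          truth = list(hr_b = hr_b, hr_p1 = hr_p1, hr_p2 = hr_p2)
        )
        truth_rows[[pid]] <- data.frame(
          id = id, condition = grp, frequency_of_viewing = freq,
          hr_b = hr_b, hr_p1 = hr_p1, hr_p2 = hr_p2,
          log_ratio_p1 = log(hr_p1 / hr_b),
          log_ratio_p2 = log(hr_p2 / hr_b)
        )
      }
    }
    truth <- do.call(rbind, truth_rows)
    cohort <- list(participants = participants, truth = truth)
    if (!is.null(out_dir)) write_cohort(cohort, out_dir)
    cohort
  })
}

# internal: write a cohort to disk (brightness CSVs + manifest + truth)
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(cohort$participants, function(p) {
    trial_path <- file.path(out_dir, paste0(p$id, "_trial.csv"))
    write_brightness_csv(p$trial_series, trial_path)
    stim_paths <- vapply(seq_along(p$stimulus_series), function(j) {
      path <- file.path(out_dir, sprintf("%s_stim%d.csv", p$id, j))
      write_brightness_csv(p$stimulus_series[[j]], path)
      path
    }, character(1))
    list(id = p$id, condition = p$condition,
         frequency_of_viewing = p$frequency_of_viewing,
         trial_series = trial_path, stimulus_series = as.list(stim_paths))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Read a cohort manifest written by [generate_cohort()]
#'
#' @param path path to a `manifest.json`.
#' @return a cohort list (participants with loaded brightness series).
#' @export
read_cohort_manifest <- function(path) {
  manifest <- jsonlite::read_json(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  participants <- lapply(manifest, function(m) {
    list(
      id = m$id, condition = m$condition,
      frequency_of_viewing = m$frequency_of_viewing,
      trial_series = read_brightness_csv(resolve(m$trial_series)),
      stimulus_series = lapply(m$stimulus_series,
                               function(p) read_brightness_csv(resolve(p)))
    )
  })
  list(participants = participants, truth = NULL)
}
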