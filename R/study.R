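#' Analysis-period definitions
#'
#' The baseline is the first 30 s of the trial recording (no stimulus on
#' screen). Each 180-s stimulus recording is split into halves; 5 s are cut
#' from the start of the first half and from the end of the second half to
#' discard band-pass filter transients, giving `[5, 90)` and `[90, 175)`
#' seconds by default.
#'
#' @param baseline numeric `c(start, end)` window of the trial recording,
#'   seconds (default `c(0, 30)`).
#' @param p1 window of the first stimulus period (default `c(5, 90)`).
#' @param p2 window of the second stimulus period (default `c(90, 175)`).
#' @return an object of class `period_spec`.
#' @export
period_spec <- function(baseline = c(0, 30), p1 = c(5, 90), p2 = c(90, 175)) {
  check <- function(w, nm) {
    if (length(w) != 2L || w[1] < 0 || w[1] >= w[2]) {
      stop(sprintf("`%s` must be a valid window c(start, end)", nm),
           call. = FALSE)
    }
  }
  check(baseline, "baseline"); check(p1, "p1"); check(p2, "p2")
  if (p1[2] > p2[1] + 1e-9) {
    stop("stimulus periods must not overlap", call. = FALSE)
  }
  structure(list(baseline = baseline, p1 = p1, p2 = p2),
            class = "period_spec")
}

#' Estimate the average heart rate over one analysis period
#'
#' Runs the full estimation chain: band-pass filter, window trim, double
#' differentiation, peak detection, pulse-to-pulse intervals, and the
#' harmonic-tolerant grid estimator. By default the whole recording is
#' filtered before the window is cut, so that the 5-s period margins
#' actually discard the filter transients; `filter_first = FALSE` trims
#' first instead.
#'
#' @param series a [brightness_series()] (one recording).
#' @param window `c(start, end)` in seconds relative to the series, or
#'   `NULL` for the whole series.
#' @param filter a [filter_spec()].
#' @param peaks a [peak_params()].
#' @param grid a [grid_spec()].
#' @param loss a [loss_config()].
#' @param filter_first filter the full series before trimming (default
#'   `TRUE`).
#' @return an `hr_estimate` (see [estimate_m_prime()]) with the
#'   pulse-to-pulse intervals attached as `$ppis`.
#' @export
estimate_period_hr <- function(series, window = NULL,
                               filter = filter_spec(),
                               peaks = peak_params(),
                               grid = grid_spec(),
                               loss = loss_config(),
                               filter_first = TRUE) {
  stopifnot(inherits(series, "brightness_series"))
  s <- series
  raw_scale <- abs(mean(s$values)) + stats::sd(s$values)
  if (filter_first) {
    s <- bandpass(s, filter)
    if (!is.null(window)) s <- trim_series(s, window[1], window[2])
  } else {
    if (!is.null(window)) s <- trim_series(s, window[1], window[2])
    s <- bandpass(s, filter)
  }
  # a (near-)constant recording leaves only filtering roundoff behind;
  # treating that as signal would hallucinate peaks
  if (stats::sd(s$values) <= 1e-4 * (raw_scale + 1)) {
    stop("insufficient signal: series has no in-band content", call. = FALSE)
  }
  d2 <- second_difference(s)
  pt <- detect_peaks(d2, peaks)
  ppis <- peaks_to_ppi(pt)
  est <- estimate_m_prime(ppis, grid, loss)
  est$ppis <- ppis
  est
}

#' Log heart-rate change ratios
#'
#' `ln(h_period / h_baseline)` for both stimulus periods: the study's
#' physiological response variables. Zero when the period rate equals
#' baseline; antisymmetric under exchanging the two rates.
#'
#' @param h_b baseline heart rate, bpm.
#' @param h_p1 first-period heart rate, bpm.
#' @param h_p2 second-period heart rate, bpm.
#' @return list with `log_ratio_p1` and `log_ratio_p2`.
#' @export
change_ratios <- function(h_b, h_p1, h_p2) {
  if (any(c(h_b, h_p1, h_p2) <= 0)) {
    stop("heart rates must be positive", call. = FALSE)
  }
  list(log_ratio_p1 = log(h_p1 / h_b), log_ratio_p2 = log(h_p2 / h_b))
}

#' Quality-control thresholds
#'
#' Conservative, configurable proxies for "clearly inaccurate or doubtful"
#' recordings. A period estimate trips QC when it has too few intervals,
#' when the loss per interval exceeds a squared-frame budget, when too many
#' intervals needed a harmonic correction (scale != 1) at the optimum, or
#' when the estimate clamped to the grid boundary. Exclusion on harmonic
#' near-ties is off by default (ties are resolved deterministically and
#' logged) but available.
#'
#' @param min_ppi minimum intervals per period (default 20).
#' @param max_loss_per_interval maximum `loss / n_ppi`, squared frames
#'   (default 4, i.e. a 2-frame RMS residual).
#' @param max_offscale_fraction maximum fraction of intervals assigned a
#'   scale other than 1 (default 0.5).
#' @param exclude_on_boundary exclude when any estimate hits the grid
#'   boundary (default `TRUE`).
#' @param exclude_on_tie exclude when any estimate flags a harmonic
#'   near-tie (default `FALSE`).
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(min_ppi = 20, max_loss_per_interval = 4,
                      max_offscale_fraction = 0.5,
                      exclude_on_boundary = TRUE, exclude_on_tie = FALSE) {
  structure(
    list(min_ppi = min_ppi, max_loss_per_interval = max_loss_per_interval,
         max_offscale_fraction = max_offscale_fraction,
         exclude_on_boundary = isTRUE(exclude_on_boundary),
         exclude_on_tie = isTRUE(exclude_on_tie)),
    class = "qc_config"
  )
}

# internal: QC reasons for one hr_estimate
qc_reasons_for_estimate <- function(est, config, label) {
  reasons <- character(0)
  if (est$n_ppi < config$min_ppi) {
    reasons <- c(reasons, sprintf("too-few-peaks:%s", label))
  }
  if (est$loss / est$n_ppi > config$max_loss_per_interval) {
    reasons <- c(reasons, sprintf("loss-threshold:%s", label))
  }
  counts <- est$scale_assignment_counts
  n_unit <- if ("1" %in% names(counts)) counts[["1"]] else 0
  off <- 1 - n_unit / est$n_ppi
  if (off > config$max_offscale_fraction) {
    reasons <- c(reasons, sprintf("offscale-fraction:%s", label))
  }
  if (config$exclude_on_boundary && est$boundary_hit) {
    reasons <- c(reasons, sprintf("boundary-hit:%s", label))
  }
  if (config$exclude_on_tie && est$tie_detected) {
    reasons <- c(reasons, sprintf("tie-detected:%s", label))
  }
  reasons
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply quality control to a participant record
#'
#' Deterministically flags a participant for exclusion from the heart-rate
#' analysis based on the diagnostics of every period estimate (baseline and
#' each stimulus period) and any estimation failures.
#'
#' @param record a `participant_record` from
#'   [participant_change_ratios()].
#' @param config a [qc_config()].
#' @return an object of class `qc_report`: list with `excluded` (logical)
#'   and `reasons` (character; non-empty iff excluded).
#' @export
apply_qc <- function(record, config = qc_config()) {
  stopifnot(inherits(record, "participant_record"))
  reasons <- character(0)
  if (length(record$failures)) {
    reasons <- c(reasons, paste0("estimation-failure:", record$failures))
  }
  ests <- c(
    list(baseline = record$estimates$baseline),
    record$estimates$p1, record$estimates$p2
  )
  labels <- c("baseline",
              paste0("p1-stim", seq_along(record$estimates$p1)),
              paste0("p2-stim", seq_along(record$estimates$p2)))
  for (i in seq_along(ests)) {
    if (is.null(ests[[i]])) next
    reasons <- c(reasons, qc_reasons_for_estimate(ests[[i]], config, labels[i]))
  }
  if (!length(record$failures) &&
      (!is.finite(record$log_ratio_p1) || !is.finite(record$log_ratio_p2))) {
    reasons <- c(reasons, "non-finite-ratio")
  }
  structure(list(excluded = length(reasons) > 0, reasons = unique(reasons)),
            class = "qc_report")
}

#' Per-participant heart rates and log change ratios
#'
#' Estimates the baseline heart rate from the trial recording, and the two
#' period rates from each stimulus recording. With
#' `aggregate = "average"` (default) period rates are estimated per
#' stimulus and averaged across stimuli; `aggregate = "pooled"` pools the
#' pulse-to-pulse intervals of all stimuli per period and runs the grid
#' estimator once. Ratios are `ln(h_p / h_b)`. QC is applied and attached.
#'
#' @param trial_series the trial-recording [brightness_series()] (baseline).
#' @param stimulus_series list of stimulus-recording
#'   [brightness_series()] (>= 1).
#' @param periods a [period_spec()].
#' @param id,condition,frequency_of_viewing participant metadata;
#'   `condition` is `"tracing"` or `"control"`, `frequency_of_viewing` an
#'   ordinal score with 0 = almost never.
#' @param aggregate `"average"` or `"pooled"` (see above).
#' @param qc a [qc_config()].
#' @param filter,peaks,grid,loss pipeline configuration, see
#'   [estimate_period_hr()].
#' @param filter_first see [estimate_period_hr()].
#' @return an object of class `participant_record`.
#' @export
participant_change_ratios <- function(trial_series, stimulus_series,
                                      periods = period_spec(),
                                      id = NA_character_,
                                      condition = NA_character_,
                                      frequency_of_viewing = NA_integer_,
                                      aggregate = c("average", "pooled"),
                                      qc = qc_config(),
                                      filter = filter_spec(),
                                      peaks = peak_params(),
                                      grid = grid_spec(),
                                      loss = loss_config(),
                                      filter_first = TRUE) {
  aggregate <- match.arg(aggregate)
  if (!is.na(condition) && !condition %in% c("tracing", "control")) {
    stop("`condition` must be \"tracing\" or \"control\"", call. = FALSE)
  }
  if (length(stimulus_series) < 1L) {
    stop("need at least one stimulus recording", call. = FALSE)
  }
  run <- function(series, window) {
    estimate_period_hr(series, window, filter = filter, peaks = peaks,
                       grid = grid, loss = loss,
                       filter_first = filter_first)
  }
  failures <- character(0)
  base_est <- tryCatch(run(trial_series, periods$baseline),
                       error = function(e) {
                         failures <<- c(failures, "baseline"); NULL
                       })
  p1_est <- vector("list", length(stimulus_series))
  p2_est <- vector("list", length(stimulus_series))
  for (j in seq_along(stimulus_series)) {
    p1_est[[j]] <- tryCatch(run(stimulus_series[[j]], periods$p1),
                            error = function(e) {
                              failures <<- c(failures, sprintf("p1-stim%d", j)); NULL
                            })
    p2_est[[j]] <- tryCatch(run(stimulus_series[[j]], periods$p2),
                            error = function(e) {
                              failures <<- c(failures, sprintf("p2-stim%d", j)); NULL
                            })
  }

  agg_rate <- function(ests) {
    ok <- !vapply(ests, is.null, logical(1))
    if (!any(ok)) return(NA_real_)
    if (aggregate == "average") {
      mean(vapply(ests[ok], function(e) e$h, numeric(1)))
    } else {
      pooled <- ppi_series(
        unlist(lapply(ests[ok], function(e) e$ppis$intervals)),
        fps = ests[ok][[1]]$fps
      )
      estimate_m_prime(pooled, grid, loss)$h
    }
  }
  h_b <- if (is.null(base_est)) NA_real_ else base_est$h
  h_p1 <- agg_rate(p1_est)
  h_p2 <- agg_rate(p2_est)
  lr1 <- if (is.na(h_b) || is.na(h_p1)) NA_real_ else log(h_p1 / h_b)
  lr2 <- if (is.na(h_b) || is.na(h_p2)) NA_real_ else log(h_p2 / h_b)

  record <- structure(
    list(
      id = id, condition = condition,
      frequency_of_viewing = frequency_of_viewing,
      h_b = h_b, h_p1 = h_p1, h_p2 = h_p2,
      log_ratio_p1 = lr1, log_ratio_p2 = lr2,
      estimates = list(baseline = base_est, p1 = p1_est, p2 = p2_est),
      failures = failures,
      qc = NULL
    ),
    class = "participant_record"
  )
  record$qc <- apply_qc(record, qc)
  record
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf(
    "<participant_record> %s (%s): h_b=%.1f h_p1=%.1f h_p2=%.1f bpm, log ratios %.4f / %.4f%s\n",
    x$id, x$condition, x$h_b, x$h_p1, x$h_p2,
    x$log_ratio_p1, x$log_ratio_p2,
    if (isTRUE(x$qc$excluded)) " [excluded]" else ""
  ))
  invisible(x)
}

#' Flatten participant records to a results data frame
#'
#' One row per participant: metadata, period heart rates, log change
#' ratios, and QC outcome (`excluded`, semicolon-joined `reasons`).
#'
#' @param records list of `participant_record`s.
#' @return a data frame.
#' @export
records_to_df <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(
      id = r$id, condition = r$condition,
      frequency_of_viewing = r$frequency_of_viewing,
      h_b = r$h_b, h_p1 = r$h_p1, h_p2 = r$h_p2,
      log_ratio_p1 = r$log_ratio_p1, log_ratio_p2 = r$log_ratio_p2,
      excluded = isTRUE(r$qc$excluded),
      reasons = paste(r$qc$reasons, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
}

#' Descriptive cohort summary by condition and viewing-frequency stratum
#'
#' Splits non-excluded participants into condition x frequency strata
#' (`low` = score 0, "almost never"; `high` = score >= 1) and reports per
#' stratum the sample size, mean and SD of the three period heart rates
#' and of both log change ratios, plus exclusion counts over all records
#' of the stratum. SD is `NA` for singleton strata.
#'
#' @param records list of `participant_record`s.
#' @return a data frame, one row per condition x frequency stratum.
#' @export
summarize_cohort <- function(records) {
  df <- records_to_df(records)
  if (!any(!df$excluded)) stop("all participants excluded", call. = FALSE)
  df$frequency_group <- ifelse(df$frequency_of_viewing == 0, "low", "high")
  strata <- unique(df[, c("condition", "frequency_group")])
  strata <- strata[order(strata$condition, strata$frequency_group), ]
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    all_s <- df[df$condition == strata$condition[i] &
                  df$frequency_group == strata$frequency_group[i], ]
    s <- all_s[!all_s$excluded, ]
    msd <- function(v) {
      if (!nrow(s)) return(c(NA_real_, NA_real_))
      c(mean(v), if (length(v) > 1) stats::sd(v) else NA_real_)
    }
    hb <- msd(s$h_b); hp1 <- msd(s$h_p1); hp2 <- msd(s$h_p2)
    l1 <- msd(s$log_ratio_p1); l2 <- msd(s$log_ratio_p2)
    data.frame(
      condition = strata$condition[i],
      frequency_group = strata$frequency_group[i],
      n = nrow(s),
      h_b_mean = hb[1], h_b_sd = hb[2],
      h_p1_mean = hp1[1], h_p1_sd = hp1[2],
      h_p2_mean = hp2[1], h_p2_sd = hp2[2],
      log_ratio_p1_mean = l1[1], log_ratio_p1_sd = l1[2],
      log_ratio_p2_mean = l2[1], log_ratio_p2_sd = l2[2],
      n_excluded = sum(all_s$excluded),
      excluded_fraction = mean(all_s$excluded)
    )
  })
  do.call(rbind, rows)
}

#' Between-condition difference in a response variable
#'
#' Welch comparison of a per-participant variable (default the
#' second-period log change ratio) between the tracing and control
#' conditions, over non-excluded participants: the recovered group effect
#' in simulation studies.
#'
#' @param records list of `participant_record`s.
#' @param variable column of [records_to_df()] to compare
#'   (default `"log_ratio_p2"`).
#' @return list with `estimate` (tracing minus control), `se`, `ci`
#'   (95% confidence interval) and the per-group means.
#' @export
group_effect <- function(records, variable = "log_ratio_p2") {
  df <- records_to_df(records)
  df <- df[!df$excluded & is.finite(df[[variable]]), ]
  x <- df[[variable]][df$condition == "tracing"]
  y <- df[[variable]][df$condition == "control"]
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least two non-excluded participants per condition",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y)
  list(
    estimate = mean(x) - mean(y),
    se = sqrt(stats::var(x) / length(x) + stats::var(y) / length(y)),
    ci = as.numeric(tt$conf.int),
    mean_tracing = mean(x),
    mean_control = mean(y)
  )
}

#' Run the full study pipeline on a cohort
#'
#' Applies [participant_change_ratios()] to every participant of a cohort
#' (e.g. from [generate_cohort()] or [read_cohort_manifest()]).
#'
#' @param cohort a cohort list with a `participants` element.
#' @param ... passed to [participant_change_ratios()].
#' @return list of `participant_record`s.
#' @export
run_study <- function(cohort, ...) {
  lapply(cohort$participants, function(p) {
    participant_change_ratios(
      p$trial_series, p$stimulus_series,
      id = p$id, condition = p$condition,
      frequency_of_viewing = p$frequency_of_viewing, ...
    )
  })
}
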