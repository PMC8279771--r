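#' Band-pass filter specification
#'
#' Defaults follow the PPG preprocessing convention of passing 0.67-3.83 Hz
#' (about 40-230 beats per minute) with a second-order Butterworth filter.
#' Zero-phase (forward-backward) application is the default so that peak
#' times are not shifted, at the cost of squaring the magnitude response.
#'
#' @param low_cut lower cutoff in Hz (default 0.67).
#' @param high_cut upper cutoff in Hz (default 3.83).
#' @param order Butterworth prototype order (default 2).
#' @param zero_phase logical; apply the filter forward and backward
#'   (default `TRUE`). When `FALSE` the filter runs causally once.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 0.67, high_cut = 3.83, order = 2,
                        zero_phase = TRUE) {
  if (!(low_cut > 0 && low_cut < high_cut)) {
    stop("require 0 < low_cut < high_cut", call. = FALSE)
  }
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  structure(
    list(low_cut = low_cut, high_cut = high_cut,
         order = as.integer(order), zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

# internal: design the digital Butterworth band-pass for a given fps
butter_bandpass <- function(spec, fps) {
  nyq <- fps / 2
  if (spec$high_cut >= nyq) {
    stop(sprintf("high cutoff %.3g Hz must be below the Nyquist frequency %.3g Hz",
                 spec$high_cut, nyq), call. = FALSE)
  }
  signal::butter(spec$order, c(spec$low_cut, spec$high_cut) / nyq, type = "pass")
}

#' Band-pass filter a brightness series
#'
#' Applies the Butterworth band-pass described by `spec` to the trace.
#' Out-of-band components (DC level, slow drift, high-frequency noise) are
#' attenuated; the output has near-zero mean.
#'
#' @param series a [brightness_series()].
#' @param spec a [filter_spec()].
#' @return a filtered [brightness_series()] of the same length.
#' @export
bandpass <- function(series, spec = filter_spec()) {
  stopifnot(inherits(series, "brightness_series"), inherits(spec, "filter_spec"))
  n <- length(series$values)
  if (n <= 3 * spec$order) {
    stop("series too short for stable filtering", call. = FALSE)
  }
  bf <- butter_bandpass(spec, series$fps)
  y <- if (spec$zero_phase) {
    # odd-reflection padding before forward-backward filtering: without it
    # the implicit zero extension sees the full DC level as a step and
    # rings far into the series. Pad length covers the slow transient of
    # the low cutoff.
    x <- series$values
    L <- min(n - 1L, as.integer(ceiling(3 * series$fps / spec$low_cut)))
    xp <- c(2 * x[1] - x[(L + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - L)])
    yp <- signal::filtfilt(bf, xp)
    yp[(L + 1L):(L + n)]
  } else {
    as.numeric(signal::filter(bf, series$values))
  }
  out <- brightness_series(y, series$fps, series$start_time)
  attr(out, "frame_offset") <- frame_offset(series)
  out
}

#' Magnitude response of the implemented band-pass filter
#'
#' Evaluates `|H(e^{-i 2 pi f / fps})|` of the designed digital filter at
#' the requested frequencies, squared when `spec$zero_phase` is on (the
#' effective gain of forward-backward filtering).
#'
#' @param spec a [filter_spec()].
#' @param fps sampling rate the filter is applied at.
#' @param freqs frequencies in Hz.
#' @return numeric vector of gains.
#' @export
filter_gain <- function(spec, fps, freqs) {
  stopifnot(inherits(spec, "filter_spec"))
  bf <- butter_bandpass(spec, fps)
  g <- vapply(freqs, function(f) {
    z <- exp(-1i * 2 * pi * f / fps)
    num <- sum(bf$b * z^(seq_along(bf$b) - 1))
    den <- sum(bf$a * z^(seq_along(bf$a) - 1))
    Mod(num / den)
  }, numeric(1))
  if (spec$zero_phase) g^2 else g
}

#' Discrete second difference of a brightness series
#'
#' Computes `y[i] = x[i+1] - 2 x[i] + x[i-1]`, the discrete analogue of the
#' second time derivative. Double differentiation sharpens the steep
#' systolic portion of each pulse so beats stand out to the peak detector.
#' The output is two frames shorter; a `frame_offset` attribute (+1 per
#' application) is carried so detected peak indices can be mapped back to
#' original-frame coordinates.
#'
#' @param series a [brightness_series()] with at least 3 frames.
#' @return a [brightness_series()] of length `length(series) - 2`.
#' @export
second_difference <- function(series) {
  stopifnot(inherits(series, "brightness_series"))
  x <- series$values
  if (length(x) < 3L) stop("need at least 3 frames to difference twice", call. = FALSE)
  y <- diff(x, differences = 2)
  out <- brightness_series(y, series$fps, series$start_time + 1 / series$fps)
  attr(out, "frame_offset") <- frame_offset(series) + 1L
  out
}
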