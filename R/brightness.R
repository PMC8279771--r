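#' Per-frame brightness series
#'
#' The central 1-D signal of the pipeline: one brightness value per video
#' frame (typically the mean red-channel intensity over the whole frame),
#' together with the frame rate and the start time of the first frame
#' relative to the recording. Frame `i` (1-based) has timestamp
#' `(i - 1) / fps` seconds relative to `start_time`; a series of `n` frames
#' spans the half-open interval `[0, n / fps)`.
#'
#' @param values numeric vector of brightness values, one per frame
#'   (arbitrary units). Must be finite.
#' @param fps frames per second (positive scalar).
#' @param start_time start of the first frame in seconds relative to the
#'   original recording. Bookkeeping only; all window arguments elsewhere
#'   are relative to the series itself.
#'
#' @return an object of class `brightness_series`: a list with elements
#'   `values`, `fps`, `start_time`.
#' @export
#' @examples
#' s <- brightness_series(sin(2 * pi * (0:299) / 30), fps = 30)
#' series_duration(s)
brightness_series <- function(values, fps, start_time = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("brightness series must contain at least one frame", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("brightness values must all be finite", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("`fps` must be a positive finite scalar", call. = FALSE)
  }
  if (!is.numeric(start_time) || length(start_time) != 1L || !is.finite(start_time)) {
    stop("`start_time` must be a finite scalar", call. = FALSE)
  }
  structure(
    list(values = values, fps = fps, start_time = start_time),
    class = "brightness_series"
  )
}

#' @export
print.brightness_series <- function(x, ...) {
  cat(sprintf(
    "<brightness_series> %d frames @ %.6g fps (%.2f s, start %.2f s)\n",
    length(x$values), x$fps, series_duration(x), x$start_time
  ))
  invisible(x)
}

#' Duration of a brightness series in seconds
#'
#' A series of `n` frames at `fps` frames/second covers `n / fps` seconds
#' (each frame occupies `1/fps` s starting at its timestamp).
#'
#' @param series a [brightness_series()].
#' @return duration in seconds.
#' @export
series_duration <- function(series) {
  stopifnot(inherits(series, "brightness_series"))
  length(series$values) / series$fps
}

#' Frame timestamps relative to the series start
#'
#' @param series a [brightness_series()].
#' @return numeric vector, `(i - 1) / fps` for each frame.
#' @export
series_times <- function(series) {
  stopifnot(inherits(series, "brightness_series"))
  (seq_along(series$values) - 1) / series$fps
}

#' Trim a brightness series to a half-open time window
#'
#' Retains the frames whose timestamps fall in `[start_time, end_time)`
#' seconds, relative to the series start. The result's `start_time` is
#' advanced so absolute timing is preserved.
#'
#' @param series a [brightness_series()].
#' @param start_time window start in seconds, `>= 0`.
#' @param end_time window end in seconds, `> start_time` and at most the
#'   series duration.
#' @return a trimmed [brightness_series()].
#' @export
#' @examples
#' s <- brightness_series(rnorm(300), fps = 30)
#' length(trim_series(s, 2, 5)$values)  # 3 s x 30 fps = 90 frames
trim_series <- function(series, start_time, end_time) {
  stopifnot(inherits(series, "brightness_series"))
  eps <- 1e-9
  if (!is.finite(start_time) || !is.finite(end_time) ||
      start_time < 0 || start_time >= end_time) {
    stop("require 0 <= start_time < end_time", call. = FALSE)
  }
  if (end_time > series_duration(series) + eps) {
    stop("window end exceeds series duration", call. = FALSE)
  }
  t <- series_times(series)
  keep <- t >= start_time - eps & t < end_time - eps
  if (!any(keep)) stop("empty trim window", call. = FALSE)
  out <- brightness_series(
    series$values[keep], series$fps,
    start_time = series$start_time + start_time
  )
  attr(out, "frame_offset") <- frame_offset(series)
  out
}

#' Resample a brightness series to a target frame rate
#'
#' Linearly interpolates the trace onto a uniform grid at `target_fps`
#' spanning the original timestamps (0 to `(n-1)/fps` s). Used to bring
#' recordings taken at arbitrary native frame rates onto the canonical
#' 30 fps grid before analysis.
#'
#' @param series a [brightness_series()] with at least two frames.
#' @param target_fps target frames per second (default 30).
#' @return a [brightness_series()] at `target_fps`.
#' @export
resample_to_fps <- function(series, target_fps = 30) {
  stopifnot(inherits(series, "brightness_series"))
  if (!is.numeric(target_fps) || length(target_fps) != 1L || target_fps <= 0) {
    stop("`target_fps` must be a positive scalar", call. = FALSE)
  }
  n <- length(series$values)
  if (n < 2L) stop("need at least two frames to resample", call. = FALSE)
  t_old <- series_times(series)
  t_new <- seq(0, t_old[n], by = 1 / target_fps)
  vals <- stats::approx(t_old, series$values, xout = t_new, method = "linear")$y
  brightness_series(vals, target_fps, series$start_time)
}

#' Write a brightness series to CSV
#'
#' Columns `frame_index` (0-based), `time_s` (absolute, i.e. including
#' `start_time`) and `brightness`, with a header row; the interchange format
#' for precomputed traces.
#'
#' @param series a [brightness_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_brightness_csv <- function(series, path) {
  stopifnot(inherits(series, "brightness_series"))
  df <- data.frame(
    frame_index = seq_along(series$values) - 1L,
    time_s = series$start_time + series_times(series),
    brightness = series$values
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a brightness series from CSV
#'
#' Expects the header `frame_index,time_s,brightness`. The frame rate is
#' recovered from the median spacing of `time_s`; the first timestamp
#' becomes `start_time`.
#'
#' @param path CSV file path.
#' @return a [brightness_series()].
#' @export
read_brightness_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame_index", "time_s", "brightness")
  if (!all(need %in% names(df))) {
    stop("brightness CSV must have columns frame_index,time_s,brightness",
         call. = FALSE)
  }
  df <- df[order(df$frame_index), , drop = FALSE]
  if (nrow(df) < 2L) {
    return(brightness_series(df$brightness, fps = 30, start_time = df$time_s[1]))
  }
  fps <- 1 / stats::median(diff(df$time_s))
  brightness_series(df$brightness, fps = fps, start_time = df$time_s[1])
}

# internal: offset (in frames) between this series' indices and the
# original-frame coordinates; bumped by second_difference().
frame_offset <- function(series) {
  off <- attr(series, "frame_offset")
  if (is.null(off)) 0L else off
}
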