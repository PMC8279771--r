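#' In-memory video: a stack of RGB frames plus optional audio
#'
#' Container for decoded fingertip-video data. `frames` is either a 4-d
#' numeric array `[height, width, channel, frame]` or a list of 3-d arrays
#' `[height, width, channel]`; channel 1 is red. An optional mono audio
#' track (used only for sync-tone location) may be attached.
#'
#' @param frames 4-d array or list of 3-d arrays as described above.
#' @param fps native frames per second.
#' @param audio optional numeric vector of audio samples.
#' @param audio_rate audio sample rate (samples/second); required when
#'   `audio` is supplied.
#' @return an object of class `raw_video`.
#' @export
raw_video <- function(frames, fps, audio = NULL, audio_rate = NULL) {
  if (is.array(frames)) {
    if (length(dim(frames)) != 4L) {
      stop("`frames` array must be [height, width, channel, frame]", call. = FALSE)
    }
    n <- dim(frames)[4]
  } else if (is.list(frames)) {
    n <- length(frames)
  } else {
    stop("`frames` must be a 4-d array or a list of 3-d arrays", call. = FALSE)
  }
  if (n < 1L) stop("video must contain at least one frame", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("`fps` must be a positive scalar", call. = FALSE)
  }
  if (!is.null(audio) && (is.null(audio_rate) || audio_rate <= 0)) {
    stop("`audio_rate` must be supplied with `audio`", call. = FALSE)
  }
  structure(
    list(frames = frames, fps = fps, n_frames = n,
         audio = audio, audio_rate = audio_rate),
    class = "raw_video"
  )
}

#' @export
print.raw_video <- function(x, ...) {
  cat(sprintf("<raw_video> %d frames @ %.6g fps%s\n", x$n_frames, x$fps,
              if (is.null(x$audio)) "" else
                sprintf(", audio @ %g Hz", x$audio_rate)))
  invisible(x)
}

# internal: frame i of a raw_video as an [h, w, c] array
video_frame <- function(video, i) {
  if (is.list(video$frames)) video$frames[[i]] else video$frames[, , , i, drop = FALSE][, , , 1]
}

#' Extract the whole-frame red-channel brightness trace from a video
#'
#' For every frame, computes the arithmetic mean of the red channel over all
#' pixels (no region of interest). The change of this "brightness" over time
#' tracks blood-volume changes in the fingertip pressed against the lens.
#'
#' @param video a [raw_video()].
#' @return a [brightness_series()] at the video's native frame rate with
#'   `start_time = 0`.
#' @export
extract_brightness <- function(video) {
  stopifnot(inherits(video, "raw_video"))
  vals <- vapply(seq_len(video$n_frames), function(i) {
    f <- video_frame(video, i)
    d <- dim(f)
    if (is.null(d) || length(d) < 3L || d[3] < 3L) {
      stop("frame has no red channel (need >= 3 colour channels)", call. = FALSE)
    }
    mean(f[, , 1])
  }, numeric(1))
  brightness_series(vals, video$fps, start_time = 0)
}

#' Sync marks: times of the first and last tone bursts
#'
#' @param start_time seconds of the first detected burst.
#' @param end_time seconds of the last detected burst.
#' @return an object of class `sync_marks`.
#' @export
sync_marks <- function(start_time, end_time) {
  if (!(start_time >= 0 && start_time < end_time)) {
    stop("require 0 <= start_time < end_time", call. = FALSE)
  }
  structure(list(start_time = start_time, end_time = end_time),
            class = "sync_marks")
}

#' Locate synchronisation tone bursts in an audio track
#'
#' The experiment plays an electronic sound at the beginning and end of each
#' stimulus presentation; the sounds are picked up by the phone's microphone
#' and mark where to cut the video. Detection is a simple envelope
#' thresholder: the rectified audio is smoothed with a moving average, and
#' samples whose envelope exceeds `threshold_k` times the median envelope
#' are grouped into bursts (gaps shorter than `min_gap` merge).
#'
#' @param audio numeric vector of audio samples.
#' @param audio_rate samples per second.
#' @param threshold_k envelope threshold as a multiple of the median
#'   envelope (default 8).
#' @param smooth_window moving-average window in seconds (default 0.02).
#' @param min_gap minimum silence between distinct bursts, seconds
#'   (default 0.25).
#' @return a [sync_marks()] with the onset times of the first and last
#'   bursts.
#' @export
locate_sync_marks <- function(audio, audio_rate, threshold_k = 8,
                              smooth_window = 0.02, min_gap = 0.25) {
  if (length(audio) == 0L) stop("audio track is empty", call. = FALSE)
  if (!is.numeric(audio_rate) || audio_rate <= 0) {
    stop("`audio_rate` must be positive", call. = FALSE)
  }
  w <- max(1L, as.integer(round(smooth_window * audio_rate)))
  env <- as.numeric(stats::filter(abs(audio), rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  thr <- threshold_k * stats::median(env)
  above <- env > thr & env > 0
  if (!any(above)) stop("sync failure: no tone bursts detected", call. = FALSE)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bs <- starts[r$values]
  be <- ends[r$values]
  # merge bursts separated by less than min_gap
  if (length(bs) > 1L) {
    keep_start <- bs[1]
    merged_s <- integer(0); merged_e <- integer(0)
    cur_s <- bs[1]; cur_e <- be[1]
    for (i in seq_along(bs)[-1]) {
      if ((bs[i] - cur_e) / audio_rate < min_gap) {
        cur_e <- be[i]
      } else {
        merged_s <- c(merged_s, cur_s); merged_e <- c(merged_e, cur_e)
        cur_s <- bs[i]; cur_e <- be[i]
      }
    }
    merged_s <- c(merged_s, cur_s); merged_e <- c(merged_e, cur_e)
    bs <- merged_s; be <- merged_e
  }
  if (length(bs) < 2L) {
    stop("sync failure: fewer than two tone bursts detected", call. = FALSE)
  }
  sync_marks((bs[1] - 1L) / audio_rate, (bs[length(bs)] - 1L) / audio_rate)
}
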