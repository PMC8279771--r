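#' Peak-detection parameters
#'
#' @param min_distance minimum separation between retained peaks, in
#'   frames. Default `NULL` resolves at detection time to
#'   `floor(fps * 60 / 230)`, one interval at the top of the 40-230 bpm
#'   pass band.
#' @param min_prominence absolute prominence threshold in signal units.
#'   Default `NULL` resolves to `prominence_mult` times the raw (unscaled)
#'   median absolute deviation of the signal.
#' @param prominence_mult multiplier for the adaptive MAD threshold
#'   (default 2). On oscillatory traces the topographic prominence of a
#'   genuine beat is about 2.5x the raw MAD, while ghost wiggles riding on
#'   a dropped beat's segment (filter leakage bracketed by deep valleys)
#'   reach about 1.5x; the default separates the two bands.
#' @param flip logical; detect local maxima of the sign-flipped signal
#'   instead (default `FALSE`).
#' @return an object of class `peak_params`.
#' @export
peak_params <- function(min_distance = NULL, min_prominence = NULL,
                        prominence_mult = 2, flip = FALSE) {
  if (!is.null(min_distance) && min_distance < 1) {
    stop("`min_distance` must be >= 1 frame", call. = FALSE)
  }
  structure(
    list(min_distance = min_distance, min_prominence = min_prominence,
         prominence_mult = prominence_mult, flip = isTRUE(flip)),
    class = "peak_params"
  )
}

# internal: topographic prominence of candidate maxima (scipy/MATLAB
# definition: height above the higher of the two bases, each base being the
# minimum between the peak and the nearest higher point on that side, or the
# signal edge).
peak_prominences <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect pulse peaks in a (second-differenced) brightness series
#'
#' Finds strict local maxima, keeps those whose topographic prominence
#' reaches the threshold, then enforces the minimum peak distance by
#' greedily retaining higher peaks first (the behaviour of the classic
#' `findpeaks`-style routines). Indices are reported in original-frame
#' coordinates (the `frame_offset` accumulated by [second_difference()] is
#' added back).
#'
#' @param series a [brightness_series()].
#' @param params a [peak_params()].
#' @return an object of class `peak_train`: list with strictly increasing
#'   1-based `indices` (original-frame coordinates) and `fps`.
#' @export
detect_peaks <- function(series, params = peak_params()) {
  stopifnot(inherits(series, "brightness_series"))
  x <- series$values
  if (params$flip) x <- -x
  n <- length(x)
  empty <- structure(list(indices = integer(0), fps = series$fps),
                     class = "peak_train")
  if (n < 3L) return(empty)

  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  if (length(cand) == 0L) return(empty)

  min_prom <- params$min_prominence
  if (is.null(min_prom)) {
    min_prom <- params$prominence_mult * stats::mad(x, constant = 1)
  }
  prom <- peak_prominences(x, cand)
  keep <- prom >= min_prom & prom > 0
  cand <- cand[keep]
  if (length(cand) == 0L) return(empty)

  min_dist <- params$min_distance
  if (is.null(min_dist)) min_dist <- max(1L, floor(series$fps * 60 / 230))
  ord <- cand[order(-x[cand], cand)]
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted) == 0L || all(abs(accepted - i) >= min_dist)) {
      accepted <- c(accepted, i)
    }
  }
  idx <- sort(accepted) + frame_offset(series)
  structure(list(indices = as.integer(idx), fps = series$fps),
            class = "peak_train")
}

#' @export
print.peak_train <- function(x, ...) {
  cat(sprintf("<peak_train> %d peaks @ %.6g fps\n", length(x$indices), x$fps))
  invisible(x)
}

#' Pulse-to-pulse interval series
#'
#' @param intervals positive numeric vector of intervals in frames.
#' @param fps frames per second the intervals are expressed in.
#' @return an object of class `ppi_series`.
#' @export
ppi_series <- function(intervals, fps) {
  intervals <- as.numeric(intervals)
  if (length(intervals) && any(!is.finite(intervals) | intervals <= 0)) {
    stop("all intervals must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("`fps` must be a positive scalar", call. = FALSE)
  }
  structure(list(intervals = intervals, fps = fps), class = "ppi_series")
}

#' Pulse-to-pulse intervals from a peak train
#'
#' `intervals[k] = indices[k+1] - indices[k]`, in frames.
#'
#' @param peaks a `peak_train` with at least two peaks.
#' @return a [ppi_series()].
#' @export
peaks_to_ppi <- function(peaks) {
  stopifnot(inherits(peaks, "peak_train"))
  if (length(peaks$indices) < 2L) {
    stop("insufficient peaks: need at least two to form an interval",
         call. = FALSE)
  }
  ppi_series(diff(peaks$indices), peaks$fps)
}
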