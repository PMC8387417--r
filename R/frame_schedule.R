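#' Dynamic-scan frame schedule
#'
#' A frame schedule is the time grid of a dynamic PET acquisition: a set of
#' contiguous, non-overlapping frames given by their start and end times in
#' minutes post-injection. Every time-activity curve in the package lives on
#' such a grid.
#'
#' @param start Numeric vector of frame start times (minutes).
#' @param end Numeric vector of frame end times (minutes), same length.
#'
#' @return An object of class `frame_schedule` with fields `start` and `end`.
#' @examples
#' s <- frame_schedule(c(0, 1, 2), c(1, 2, 4))
#' total_duration(s)
#' @export
frame_schedule <- function(start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != length(end)) {
    stop("'start' and 'end' must have the same length")
  }
  if (length(start)) {
    if (any(!is.finite(start)) || any(!is.finite(end))) {
      stop("frame times must be finite")
    }
    if (any(end <= start)) stop("every frame must have positive duration")
    if (length(start) > 1L) {
      gap <- start[-1L] - end[-length(end)]
      if (any(abs(gap) > 1e-9)) {
        stop("frames must be contiguous and non-overlapping")
      }
    }
    if (start[1L] < 0) stop("schedule must not start before time 0")
  }
  structure(list(start = start, end = end), class = "frame_schedule")
}

#' Default 60-minute dynamic framing protocol
#'
#' The acquisition grid used throughout: 60 frames of 3 s, 12 of 1 min,
#' 3 of 5 min and 3 of 10 min, for a 60-min scan. A shorter `total` keeps
#' only the frames that fit (e.g. a scan terminated early at 55 min).
#'
#' @param total Scan length in minutes to retain (default 60).
#' @return A [frame_schedule].
#' @examples
#' total_duration(default_frame_schedule())      # 60
#' total_duration(default_frame_schedule(55))    # truncated scan
#' @export
default_frame_schedule <- function(total = 60) {
  durations <- c(rep(3 / 60, 60), rep(1, 12), rep(5, 3), rep(10, 3))
  end <- cumsum(durations)
  start <- c(0, end[-length(end)])
  keep <- start < total - 1e-9
  # a frame interrupted by the scan end is kept as a shorter frame
  frame_schedule(start[keep], pmin(end[keep], total))
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule: %d frames, %.4g min total>\n",
              n_frames(x), total_duration(x)))
  invisible(x)
}

#' Number of frames in a schedule
#' @param s A [frame_schedule].
#' @return Integer frame count.
#' @export
n_frames <- function(s) length(s$start)

#' Frame midpoints
#' @param s A [frame_schedule].
#' @return Numeric vector of frame midpoints in minutes (empty for an empty
#'   schedule).
#' @export
frame_midpoints <- function(s) (s$start + s$end) / 2

#' Frame durations
#' @param s A [frame_schedule].
#' @return Numeric vector of frame durations in minutes.
#' @export
frame_durations <- function(s) s$end - s$start

#' Total scan duration
#' @param s A [frame_schedule].
#' @return Sum of frame durations in minutes (0 for an empty schedule).
#' @export
total_duration <- function(s) sum(frame_durations(s))
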