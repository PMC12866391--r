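#' Frame schedules for dynamic PET acquisitions
#'
#' A frame schedule records when each time frame of a dynamic acquisition
#' starts and how long it lasts.  Frames are contiguous and half-open:
#' frame i covers `[start, start + duration)` seconds post-injection, and
#' frame durations must be non-decreasing (clinical protocols lengthen
#' frames as count rates drop).
#'
#' `frame_schedule()` validates an explicit duration vector.
#' `default_frame_schedule()` returns the canonical 60-minute, 28-frame
#' clinical schedule whose durations step up from 30 s to 10 min:
#' 12 x 30 s, 6 x 60 s, 4 x 120 s, 4 x 300 s, 2 x 600 s.
#'
#' @param durations_s Frame durations in seconds; positive, non-decreasing.
#' @return A tibble of class `frame_schedule` with columns `frame`,
#'   `start_s`, `duration_s` and `midpoint_min` (frame midpoint, minutes).
#' @examples
#' fs <- default_frame_schedule()
#' nrow(fs)            # 28
#' sum(fs$duration_s)  # 3600
#' @export
frame_schedule <- function(durations_s) {
  durations_s <- as.numeric(durations_s)
  if (length(durations_s) < 1 || anyNA(durations_s)) {
    abort("`durations_s` must be a non-empty numeric vector.")
  }
  if (any(durations_s <= 0)) abort("Frame durations must be positive.")
  if (is.unsorted(durations_s)) {
    abort("Frame durations must be non-decreasing over the acquisition.")
  }
  starts <- cumsum(c(0, durations_s[-length(durations_s)]))
  out <- tibble(
    frame = seq_along(durations_s),
    start_s = starts,
    duration_s = durations_s,
    midpoint_min = (starts + durations_s / 2) / 60
  )
  class(out) <- c("frame_schedule", class(out))
  out
}

# canonical clinical partition: 28 frames, 30 s -> 10 min, 60 min total
.canonical_durations <- c(rep(30, 12), rep(60, 6), rep(120, 4),
                          rep(300, 4), rep(600, 2))

#' @rdname frame_schedule
#' @export
default_frame_schedule <- function() frame_schedule(.canonical_durations)

#' Construct a frame schedule from acquisition constraints
#'
#' Builds a non-decreasing sequence of `n_frames` durations running from
#' `d_min` to `d_max` seconds and summing to `total_s`.  When the canonical
#' 28-frame clinical partition (see [default_frame_schedule()]) satisfies
#' the constraints it is returned; otherwise a back-fill construction is
#' used: all frames start at `d_min` and frames are lengthened from the end
#' of the acquisition towards the front until the total is reached.
#'
#' @param n_frames Number of frames.
#' @param total_s Total acquisition length in seconds.
#' @param d_min,d_max Shortest and longest admissible frame duration (s).
#' @return A [frame_schedule()].
#' @examples
#' make_frame_schedule()                  # canonical 28-frame schedule
#' make_frame_schedule(1, 60, 60, 60)     # single 60 s frame
#' @export
make_frame_schedule <- function(n_frames = 28, total_s = 3600,
                                d_min = 30, d_max = 600) {
  if (n_frames < 1) abort("`n_frames` must be at least 1.")
  if (d_min > d_max) abort("`d_min` must not exceed `d_max`.")
  if (total_s < n_frames * d_min || total_s > n_frames * d_max) {
    abort(sprintf(
      "No schedule with %d frames of %g-%g s can sum to %g s.",
      n_frames, d_min, d_max, total_s
    ))
  }
  cd <- .canonical_durations
  if (n_frames == length(cd) && sum(cd) == total_s &&
      cd[1] == d_min && cd[length(cd)] == d_max) {
    return(frame_schedule(cd))
  }
  # back-fill greedy: lengthen frames from the end until the budget is met
  d <- rep(d_min, n_frames)
  extra <- total_s - sum(d)
  i <- n_frames
  while (extra > 0 && i >= 1) {
    step <- min(d_max - d[i], extra)
    d[i] <- d[i] + step
    extra <- extra - step
    i <- i - 1
  }
  frame_schedule(d)
}

assert_frame_schedule <- function(x, arg = "schedule") {
  if (!inherits(x, "frame_schedule")) {
    abort(sprintf("`%s` must be a frame_schedule object.", arg))
  }
  invisible(x)
}
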