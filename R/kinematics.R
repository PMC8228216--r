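## CASA-style track kinematics: curvilinear (VCL), straight-line (VSL) and
## average-path (VAP) velocity, plus straightness (STR = VSL/VAP * 100) and
## linearity (LIN = VSL/VCL * 100) scores, from raw 2-D coordinates.

#' Construct a sperm track
#'
#' A track is one cell's time-ordered 2-D trajectory in micrometres, together
#' with its identity labels and the tracker's elongation score (used downstream
#' to screen out non-sperm debris).
#'
#' @param track_id,male_id identifiers.
#' @param island,year labels for the sampling event (island-year combination).
#' @param frame integer vector of frame indices, strictly increasing.
#' @param x,y numeric coordinate vectors in micrometres.
#' @param elongation dimensionless elongation score reported by the tracker.
#' @return An object of class `sperm_track`.
#' @export
sperm_track <- function(track_id, male_id = NA_character_, island = NA_character_,
                        year = NA_character_, frame, x, y, elongation = NA_real_) {
  frame <- as.integer(frame)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(frame)
  if (n < 2L) stopf("track '%s': a track needs at least 2 points", track_id)
  if (length(x) != n || length(y) != n)
    stopf("track '%s': frame, x and y must have equal length", track_id)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("track '%s': coordinates must be finite", track_id)
  if (any(diff(frame) <= 0L))
    stopf("track '%s': frame indices must be strictly increasing", track_id)
  structure(list(track_id = as.character(track_id),
                 male_id = as.character(male_id),
                 island = as.character(island), year = as.character(year),
                 frame = frame, x = x, y = y,
                 elongation = as.numeric(elongation)),
            class = "sperm_track")
}

#' @export
print.sperm_track <- function(x, ...) {
  cat(sprintf("<sperm_track %s> male %s, %d points, frames %d-%d, elongation %s\n",
              x$track_id, x$male_id, length(x$frame),
              min(x$frame), max(x$frame), format(x$elongation)))
  invisible(x)
}

#' Frame-to-frame step distances of a track
#'
#' @param track a [sperm_track()].
#' @return Numeric vector of Euclidean distances between consecutive points,
#'   length `n_points - 1`.
#' @export
step_distances <- function(track) {
  stopifnot(inherits(track, "sperm_track"))
  sqrt(diff(track$x)^2 + diff(track$y)^2)
}

#' Smooth a track with a centred moving average
#'
#' Produces the "average path" whose length defines VAP. The window is
#' truncated symmetrically at the track ends, so the first and last smoothed
#' points coincide with the raw endpoints and output length equals input
#' length.
#'
#' @param track a [sperm_track()].
#' @param window odd positive integer window width (frames). `window = 1` is
#'   the identity.
#' @return A two-column matrix (x, y) of smoothed coordinates.
#' @export
smooth_path <- function(track, window = 5L) {
  stopifnot(inherits(track, "sperm_track"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stopf("'window' must be an odd positive integer, got %s", format(window))
  n <- length(track$x)
  half <- (window - 1L) %/% 2L
  out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("x", "y")))
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)   # symmetric truncation at the ends
    idx <- (i - h):(i + h)
    out[i, 1L] <- mean(track$x[idx])
    out[i, 2L] <- mean(track$y[idx])
  }
  out
}

#' Compute track kinematics
#'
#' VCL is the summed point-to-point path length divided by elapsed time (the
#' actual tracked point-to-point velocity); VSL the first-to-last straight
#' distance over elapsed time; VAP the length of the moving-average smoothed
#' path over elapsed time. Elapsed time is `(n_points - 1) / frame_rate` so a
#' constant-speed track reports its true speed. Ratios with zero denominators
#' are returned as `NA` and flagged, never silently zeroed.
#'
#' @param track a [sperm_track()].
#' @param frame_rate recording frame rate in Hz (default 50).
#' @param vap_window odd moving-average window for the average path
#'   (default 5 frames).
#' @return An object of class `kinematics_result`: a list with `vcl`, `vsl`,
#'   `vap` (micrometres/second), `str_score`, `lin_score` (percent, `NA` when
#'   undefined), `n_points`, `duration` (s), `step_mean`, `step_sd`,
#'   `step_max` (micrometres), and `continuous` (no frame-index gaps).
#' @export
compute_kinematics <- function(track, frame_rate = 50, vap_window = 5L) {
  stopifnot(inherits(track, "sperm_track"))
  check_number(frame_rate, "frame_rate", min = 0, strict_min = TRUE)
  steps <- step_distances(track)
  n <- length(track$x)
  elapsed <- (n - 1L) / frame_rate
  vcl <- sum(steps) / elapsed
  vsl <- sqrt((track$x[n] - track$x[1L])^2 + (track$y[n] - track$y[1L])^2) / elapsed
  sm <- smooth_path(track, vap_window)
  vap <- sum(sqrt(diff(sm[, 1L])^2 + diff(sm[, 2L])^2)) / elapsed
  str_score <- if (vap > 0) vsl / vap * 100 else NA_real_
  lin_score <- if (vcl > 0) vsl / vcl * 100 else NA_real_
  structure(list(
    track_id = track$track_id,
    vcl = vcl, vsl = vsl, vap = vap,
    str_score = str_score, lin_score = lin_score,
    n_points = n, duration = elapsed,
    step_mean = mean(steps),
    step_sd = stats::sd(steps),   # sample SD, n-1 denominator
    step_max = max(steps),
    continuous = all(diff(track$frame) == 1L)
  ), class = "kinematics_result")
}

#' @export
print.kinematics_result <- function(x, ...) {
  cat(sprintf(
    "<kinematics %s> VCL %.2f  VSL %.2f  VAP %.2f um/s | STR %s  LIN %s | %d pts, %.3f s%s\n",
    x$track_id, x$vcl, x$vsl, x$vap,
    ifelse(is.na(x$str_score), "NA", sprintf("%.1f", x$str_score)),
    ifelse(is.na(x$lin_score), "NA", sprintf("%.1f", x$lin_score)),
    x$n_points, x$duration, if (x$continuous) "" else " [gaps]"))
  invisible(x)
}

#' Nominal recording duration
#'
#' The duration a recording of `frames` frames at `frame_rate` Hz nominally
#' spans (frames / rate), as quoted for the recording configuration; velocity
#' denominators instead use inter-point time, see [compute_kinematics()].
#'
#' @param frames number of frames tracked.
#' @param frame_rate frame rate in Hz.
#' @return Duration in seconds.
#' @export
nominal_duration <- function(frames, frame_rate = 50) {
  check_number(frames, "frames", min = 1)
  check_number(frame_rate, "frame_rate", min = 0, strict_min = TRUE)
  frames / frame_rate
}
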