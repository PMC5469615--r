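#' Locomotor speed from a position trace
#'
#' Speed as the rate of body-position change: Euclidean displacement divided
#' by the time step for each adjacent sample pair. Invariant under translation
#' and rotation of the coordinate frame.
#'
#' @param p a [position_trace()].
#' @param median_filter optional odd window length for a running median on
#'   the positions before differencing (tracking-noise suppression);
#'   `NULL` (default) applies no smoothing.
#' @return A list of class `speed_trace` with `times` (midpoints of sample
#'   pairs, length n-1) and `speed` (cm/s).
#' @export
speed_from_positions <- function(p, median_filter = NULL) {
  stopifnot(inherits(p, "position_trace"))
  if (length(p$times) < 2L) stop("need at least two position samples")
  xy <- p$xy
  if (!is.null(median_filter)) {
    stopifnot(median_filter %% 2 == 1)
    xy <- apply(xy, 2, stats::runmed, k = median_filter)
  }
  dt <- diff(p$times)
  if (any(dt == 0)) stop("duplicate position timestamps")
  disp <- sqrt(rowSums(diff(xy)^2))
  structure(list(times = p$times[-length(p$times)] + dt / 2,
                 speed = disp / dt),
            class = "speed_trace")
}

#' Per-trial mean speed in the post-cue window
#'
#' Mean locomotor speed over the 4 s window following each cue onset (the
#' window in which conditioned locomotor suppression is scored). Trials whose
#' window is not fully covered by the speed trace are excluded with a
#' warning. Block averaging of the per-trial values is done with
#' [block_average()] (5 trials for aversive sessions, 10 for appetitive).
#'
#' @param s a `speed_trace` from [speed_from_positions()].
#' @param events an [event_stream()]; `label` selects the cue.
#' @param label cue label, or `NULL` for all events.
#' @param window `c(start, end)` (s relative to cue onset), default `c(0, 4)`.
#' @return Numeric vector of per-trial mean speeds (cm/s).
#' @export
cue_window_speed <- function(s, events, label = "cue", window = c(0, 4)) {
  stopifnot(inherits(s, "speed_trace"), inherits(events, "event_stream"))
  if (!is.null(label)) events <- events_with_label(events, label)
  if (!nrow(events)) stop("no cue events")
  out <- rep(NA_real_, nrow(events))
  for (k in seq_len(nrow(events))) {
    lo <- events$onset[k] + window[1]
    hi <- events$onset[k] + window[2]
    if (lo < min(s$times) || hi > max(s$times)) {
      warning(sprintf("trial %d: speed window truncated; excluded", k))
      next
    }
    out[k] <- mean(s$speed[s$times >= lo & s$times <= hi])
  }
  out[!is.na(out)]
}
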