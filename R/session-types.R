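#' Continuous fluorescence recording
#'
#' A single-channel continuous trace (e.g. GCaMP fluorescence collected through
#' an optical fiber) with its sampling rate. Time is in seconds everywhere; the
#' sampling rate is stored explicitly and never inferred from timestamps.
#'
#' @param trace numeric vector of samples (arbitrary fluorescence units).
#' @param rate sampling frequency in Hz (photometry sessions are typically
#'   digitized at 500 Hz).
#' @param t0 time of the first sample in seconds.
#' @param channel_label free-text channel description.
#' @return An object of class `recording` with fields `trace`, `rate`, `t0`,
#'   `channel_label`.
#' @examples
#' rec <- recording(rnorm(1000, 1), rate = 500)
#' recording_times(rec)[1:3]
#' @export
recording <- function(trace, rate, t0 = 0, channel_label = "fluorescence") {
  assert_scalar_pos(rate, "rate")
  trace <- as.numeric(trace)
  if (length(trace) < 1L) stop("trace must contain at least one sample")
  if (anyNA(trace)) stop("trace contains NA samples")
  structure(list(trace = trace, rate = rate, t0 = as.numeric(t0),
                 channel_label = as.character(channel_label)),
            class = "recording")
}

#' Sample times of a recording
#' @param rec a [recording()].
#' @return numeric vector `t0 + (0:(n-1))/rate` in seconds.
#' @export
recording_times <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  rec$t0 + (seq_along(rec$trace) - 1) / rec$rate
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d samples at %g Hz (%.1f s from t0=%g s)\n",
              x$channel_label, length(x$trace), x$rate,
              length(x$trace) / x$rate, x$t0))
  invisible(x)
}

#' Behavioural event stream
#'
#' Ordered behavioural events (cue onsets, infusions, footshocks, attack
#' bouts, light pulses, ...). Durations are carried explicitly -- a 2 s cue is
#' one event of duration 2, not an on/off pair.
#'
#' @param onset numeric vector of onsets (s), non-decreasing.
#' @param label character vector of event labels.
#' @param duration numeric vector of durations (s), all `>= 0`.
#' @return A data frame of class `event_stream` with columns `onset`, `label`,
#'   `duration`.
#' @examples
#' ev <- event_stream(c(10, 130), c("quinine", "quinine"), 0.5)
#' subset(ev, label == "quinine")
#' @export
event_stream <- function(onset = numeric(), label = character(),
                         duration = numeric()) {
  n <- max(length(onset), length(label), length(duration))
  if (n > 0L) {
    onset <- as.numeric(rep_len(onset, n))
    label <- as.character(rep_len(label, n))
    duration <- as.numeric(rep_len(duration, n))
  } else {
    onset <- numeric(); label <- character(); duration <- numeric()
  }
  if (length(onset) > 1L && any(diff(onset) < 0)) {
    bad <- which(diff(onset) < 0)[1L] + 1L
    stop(sprintf("event onsets must be non-decreasing (first violation at row %d)", bad))
  }
  if (any(duration < 0)) stop("event durations must be >= 0")
  structure(data.frame(onset = onset, label = label, duration = duration,
                       stringsAsFactors = FALSE),
            class = c("event_stream", "data.frame"))
}

#' Select events by label
#' @param events an [event_stream()].
#' @param label label(s) to keep.
#' @return An `event_stream` restricted to the given labels.
#' @export
events_with_label <- function(events, label) {
  stopifnot(inherits(events, "event_stream"))
  event_stream(events$onset[events$label %in% label],
               events$label[events$label %in% label],
               events$duration[events$label %in% label])
}

#' Sorted single-unit spike train
#'
#' A spike-sorted unit: spike timestamps, the per-channel mean spike waveform,
#' and (for optogenetic tagging sessions) the light-pulse train. When the unit
#' was recorded during photostimulation, `waveform_evoked` holds the mean
#' waveform of light-evoked spikes so the waveform-correlation criterion can
#' be applied.
#'
#' @param spike_times strictly increasing spike timestamps (s).
#' @param waveform_mean numeric matrix (channels x samples) or vector, mean
#'   spike waveform in microvolts.
#' @param unit_id unit identifier.
#' @param light_pulses `NULL`, or `list(onsets = <numeric>, width = <s>)`.
#' @param waveform_evoked optional mean waveform of light-evoked spikes, same
#'   shape as `waveform_mean`.
#' @param duration observation span of the recording (s); defaults to the last
#'   spike or pulse time.
#' @return An object of class `spike_unit`.
#' @export
spike_unit <- function(spike_times, waveform_mean = numeric(), unit_id = "u1",
                       light_pulses = NULL, waveform_evoked = NULL,
                       duration = NULL) {
  spike_times <- as.numeric(spike_times)
  bad <- first_nonincreasing(spike_times)
  if (bad) stop(sprintf("spike_times must be strictly increasing (violation at index %d)", bad))
  if (length(waveform_mean) && !all(is.finite(waveform_mean)))
    stop("waveform_mean must be finite")
  if (!is.null(light_pulses)) {
    stopifnot(is.list(light_pulses), !is.null(light_pulses$onsets))
    if (length(light_pulses$onsets) && (is.null(light_pulses$width) ||
                                        light_pulses$width <= 0))
      stop("light pulse width must be > 0 when pulses are present")
    light_pulses$onsets <- as.numeric(light_pulses$onsets)
  }
  if (is.null(duration))
    duration <- max(c(spike_times, light_pulses$onsets, 0))
  structure(list(spike_times = spike_times, waveform_mean = waveform_mean,
                 unit_id = as.character(unit_id), light_pulses = light_pulses,
                 waveform_evoked = waveform_evoked,
                 duration = as.numeric(duration)),
            class = "spike_unit")
}

#' @export
print.spike_unit <- function(x, ...) {
  cat(sprintf("<spike_unit> %s: %d spikes over %.1f s (%.2f spikes/s)%s\n",
              x$unit_id, length(x$spike_times), x$duration,
              if (x$duration > 0) length(x$spike_times) / x$duration else 0,
              if (!is.null(x$light_pulses) && length(x$light_pulses$onsets))
                sprintf(", %d light pulses", length(x$light_pulses$onsets))
              else ""))
  invisible(x)
}

#' Animal position trace from video tracking
#'
#' @param times strictly increasing sample times (s).
#' @param xy two-column matrix of planar coordinates (cm).
#' @return An object of class `position_trace`.
#' @export
position_trace <- function(times, xy) {
  times <- as.numeric(times)
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("xy must have two columns (x, y)")
  if (nrow(xy) != length(times)) stop("times and xy must have equal lengths")
  bad <- first_nonincreasing(times)
  if (bad) stop(sprintf("position times must be strictly increasing (violation at index %d)", bad))
  structure(list(times = times, xy = xy), class = "position_trace")
}

#' Assemble a session container
#'
#' Bundles one photometry recording and/or spike units with the behavioural
#' event log and optional position trace, the unit the readers and writers
#' operate on.
#'
#' @param recording a [recording()] or `NULL`.
#' @param events an [event_stream()].
#' @param units list of [spike_unit()] objects (possibly empty).
#' @param position a [position_trace()] or `NULL`.
#' @return An object of class `session`.
#' @export
session <- function(recording = NULL, events = event_stream(),
                    units = list(), position = NULL) {
  if (!is.null(recording)) stopifnot(inherits(recording, "recording"))
  stopifnot(inherits(events, "event_stream"))
  stopifnot(all(vapply(units, inherits, TRUE, "spike_unit")))
  if (!is.null(position)) stopifnot(inherits(position, "position_trace"))
  if (length(units) && is.null(names(units)))
    names(units) <- vapply(units, `[[`, "", "unit_id")
  structure(list(recording = recording, events = events, units = units,
                 position = position), class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat("<session>\n")
  if (!is.null(x$recording)) { cat("  "); print(x$recording) }
  cat(sprintf("  events: %d (%s)\n", nrow(x$events),
              paste(unique(x$events$label), collapse = ", ")))
  if (length(x$units)) cat(sprintf("  units: %d\n", length(x$units)))
  if (!is.null(x$position)) cat(sprintf("  position: %d samples\n",
                                        length(x$position$times)))
  invisible(x)
}
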