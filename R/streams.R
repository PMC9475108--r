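#' Regularly sampled data stream
#'
#' Container for a single-channel, regularly sampled signal together with the
#' per-sample timestamps read from the clock of the device that produced it.
#' Timestamps are in seconds on that device's local clock; the clock is
#' identified by `clock_id` so streams can later be mapped into a common
#' timeline with [map_timeline()].
#'
#' @param name Stream name (character scalar).
#' @param clock_id Identifier of the clock that produced the timestamps.
#' @param nominal_rate Nominal sampling rate in Hz.
#' @param timestamps Numeric vector of per-sample timestamps (seconds,
#'   non-decreasing).
#' @param values Numeric vector of sample values, same length as `timestamps`.
#'
#' @return An object of class `sampled_stream`.
#' @seealso [marker_stream()], [clock_offset_series()]
#' @export
#' @examples
#' s <- sampled_stream("eeg", "eeg_clock", 250, seq(0, 1, by = 1 / 250),
#'                     sin(seq(0, 1, by = 1 / 250)))
#' s
sampled_stream <- function(name, clock_id, nominal_rate, timestamps, values) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(clock_id), length(clock_id) == 1L)
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1L || nominal_rate <= 0) {
    stop("`nominal_rate` must be a single positive number", call. = FALSE)
  }
  timestamps <- as.numeric(timestamps)
  values <- as.numeric(values)
  if (length(timestamps) != length(values)) {
    stop("`timestamps` and `values` must have equal length", call. = FALSE)
  }
  if (length(timestamps) > 1L && any(diff(timestamps) < 0)) {
    stop("`timestamps` must be non-decreasing", call. = FALSE)
  }
  structure(
    list(name = name, clock_id = clock_id, nominal_rate = nominal_rate,
         timestamps = timestamps, values = values),
    class = "sampled_stream"
  )
}

#' Irregular event-marker stream
#'
#' Container for an irregular stream of labeled events (e.g. software markers
#' emitted at stimulus onsets), timestamped on the emitting device's clock.
#'
#' @param name Stream name.
#' @param clock_id Identifier of the clock that produced the timestamps.
#' @param timestamps Numeric vector of event times (seconds, strictly
#'   increasing).
#' @param labels Character vector of event labels, same length as
#'   `timestamps`.
#'
#' @return An object of class `marker_stream`.
#' @export
marker_stream <- function(name, clock_id, timestamps, labels) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(clock_id), length(clock_id) == 1L)
  timestamps <- as.numeric(timestamps)
  labels <- as.character(labels)
  if (length(timestamps) != length(labels)) {
    stop("`timestamps` and `labels` must have equal length", call. = FALSE)
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop("marker `timestamps` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(name = name, clock_id = clock_id, timestamps = timestamps,
         labels = labels),
    class = "marker_stream"
  )
}

#' Series of clock-correction offset measurements
#'
#' Timestamped measurements of the momentary offset between two device
#' clocks, as produced by an NTP-style round-trip protocol.  The offset is
#' stored as *receiver minus sender* local time, so that adding the offset to
#' a sender-clock timestamp maps it into the receiver's timeline (the
#' convention used by [map_timeline()]).
#'
#' @param receiver_clock_id,sender_clock_id Clock identifiers.
#' @param times Measurement times in seconds on the receiver clock, strictly
#'   increasing.
#' @param offsets Measured offsets in seconds (receiver minus sender), same
#'   length as `times`.
#'
#' @return An object of class `clock_offset_series`.
#' @export
clock_offset_series <- function(receiver_clock_id, sender_clock_id, times,
                                offsets) {
  stopifnot(is.character(receiver_clock_id), length(receiver_clock_id) == 1L,
            is.character(sender_clock_id), length(sender_clock_id) == 1L)
  times <- as.numeric(times)
  offsets <- as.numeric(offsets)
  if (length(times) != length(offsets)) {
    stop("`times` and `offsets` must have equal length", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("offset measurement `times` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(receiver_clock_id = receiver_clock_id,
         sender_clock_id = sender_clock_id,
         times = times, offsets = offsets),
    class = "clock_offset_series"
  )
}

#' Complete recording bundle
#'
#' Bundles all streams of one simulated (or imported) recording session:
#' audio signal, event markers, EEG stream, the clock-offset series measured
#' between the receiver and each remote clock, and -- for simulated sessions
#' -- the ground truth (true onsets and per-trial latency components) and the
#' session seed.
#'
#' @param audio_stream A [sampled_stream()] or `NULL`.
#' @param marker_stream A [marker_stream()].
#' @param eeg_stream A [sampled_stream()] or `NULL`.
#' @param offsets Named list of [clock_offset_series()] objects, keyed by
#'   sender clock id.
#' @param ground_truth List of ground-truth records (may be `NULL` for
#'   imported data).
#' @param config The session configuration that produced the bundle (or
#'   `NULL`).
#' @param seed Integer session seed (or `NA`).
#'
#' @return An object of class `recording_bundle`.
#' @export
recording_bundle <- function(audio_stream = NULL, marker_stream = NULL,
                             eeg_stream = NULL, offsets = list(),
                             ground_truth = NULL, config = NULL, seed = NA) {
  if (!is.null(audio_stream)) stopifnot(inherits(audio_stream, "sampled_stream"))
  if (!is.null(eeg_stream)) stopifnot(inherits(eeg_stream, "sampled_stream"))
  if (!is.null(marker_stream)) stopifnot(inherits(marker_stream, "marker_stream"))
  stopifnot(is.list(offsets))
  for (o in offsets) stopifnot(inherits(o, "clock_offset_series"))
  if (!is.null(ground_truth) && !is.null(marker_stream) &&
      !is.null(ground_truth$onsets) &&
      length(ground_truth$onsets) != length(marker_stream$timestamps)) {
    stop("ground-truth trial count must equal marker count", call. = FALSE)
  }
  structure(
    list(audio_stream = audio_stream, marker_stream = marker_stream,
         eeg_stream = eeg_stream, offsets = offsets,
         ground_truth = ground_truth, config = config, seed = seed),
    class = "recording_bundle"
  )
}

#' @export
print.sampled_stream <- function(x, ...) {
  n <- length(x$timestamps)
  span <- if (n) sprintf("%.3f..%.3f s", x$timestamps[1L], x$timestamps[n]) else "empty"
  cat(sprintf("<sampled_stream> '%s' on clock '%s': %d samples @ %g Hz (%s)\n",
              x$name, x$clock_id, n, x$nominal_rate, span))
  invisible(x)
}

#' @export
print.marker_stream <- function(x, ...) {
  cat(sprintf("<marker_stream> '%s' on clock '%s': %d events\n",
              x$name, x$clock_id, length(x$timestamps)))
  invisible(x)
}

#' @export
print.clock_offset_series <- function(x, ...) {
  cat(sprintf("<clock_offset_series> %s vs %s: %d measurements\n",
              x$receiver_clock_id, x$sender_clock_id, length(x$times)))
  invisible(x)
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat("<recording_bundle>\n")
  for (nm in c("audio_stream", "marker_stream", "eeg_stream")) {
    if (!is.null(x[[nm]])) {
      cat("  "); print(x[[nm]])
    }
  }
  for (o in x$offsets) {
    cat("  "); print(o)
  }
  if (!is.null(x$ground_truth)) {
    cat(sprintf("  ground truth: %d trials, seed %s\n",
                length(x$ground_truth$onsets), format(x$seed)))
  }
  invisible(x)
}
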