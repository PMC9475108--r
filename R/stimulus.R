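#' Rectangular-pulse stimulus schedule
#'
#' Describes the test stimulus: rectangular pulses of width `pulse_width`
#' repeated at `pulse_rate` over a session of length `duration`.  The study
#' conditions are 60 ms pulses at 1 Hz, played for 15 min (900 trials) or
#' 3 h (10,800 trials).
#'
#' @param pulse_width Pulse width, seconds (default 0.060).
#' @param pulse_rate Pulse repetition rate, Hz (default 1).
#' @param duration Session duration, seconds.
#' @param amplitude Pulse amplitude, arbitrary units (default 1).
#' @param first_onset Time of the first pulse onset, seconds (default 0).
#'
#' @return An object of class `stimulus_schedule`.
#' @export
#' @examples
#' sched <- stimulus_schedule(duration = 900)
#' length(generate_stimulus_onsets(sched))  # 900
stimulus_schedule <- function(pulse_width = 0.060, pulse_rate = 1,
                              duration = 900, amplitude = 1,
                              first_onset = 0) {
  if (!is.finite(pulse_rate) || pulse_rate <= 0) {
    stop("`pulse_rate` must be positive", call. = FALSE)
  }
  if (!is.finite(duration) || duration < 0) {
    stop("`duration` must be non-negative", call. = FALSE)
  }
  if (!is.finite(pulse_width) || pulse_width <= 0 ||
      pulse_width >= 1 / pulse_rate) {
    stop("`pulse_width` must be positive and shorter than the pulse period",
         call. = FALSE)
  }
  structure(
    list(pulse_width = pulse_width, pulse_rate = pulse_rate,
         duration = duration, amplitude = amplitude,
         first_onset = first_onset),
    class = "stimulus_schedule"
  )
}

#' Enumerate stimulus onset times
#'
#' Returns the true-time onsets of all pulses strictly inside
#' `[first_onset, duration)`: `first_onset`, `first_onset + 1/rate`, ...
#' A 900 s session at 1 Hz therefore has exactly 900 onsets and a 10,800 s
#' session 10,800.
#'
#' @param schedule A [stimulus_schedule()].
#' @return Numeric vector of onset times, seconds.
#' @export
generate_stimulus_onsets <- function(schedule) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  span <- schedule$duration - schedule$first_onset
  if (span <= 0) return(numeric(0))
  period <- 1 / schedule$pulse_rate
  # onsets k*period strictly below `span`; tolerate representation error at
  # the boundary so an integer number of periods is counted exactly
  n <- ceiling(span / period - 1e-9)
  schedule$first_onset + (seq_len(n) - 1) * period
}

#' Render a rectangular-pulse waveform
#'
#' Samples the analog stimulus on a regular true-time grid: the value is
#' `amplitude` on each half-open pulse interval `[onset, onset + width)` and
#' 0 elsewhere.
#'
#' @param onsets Sorted numeric vector of pulse onset times, seconds.
#' @param schedule A [stimulus_schedule()] providing width and amplitude.
#' @param rate Sampling rate of the rendered waveform, Hz.  Should be well
#'   above `2 / pulse_width`.
#' @param t_start,t_end Span of the rendered grid (defaults: 0 and
#'   `schedule$duration`); the sample count is `round((t_end - t_start) * rate)`.
#' @param clock_id Clock identifier attached to the stream (the analog
#'   signal is observed on the reference/receiver timeline).
#' @return A [sampled_stream()].
#' @export
render_square_wave <- function(onsets, schedule, rate,
                               t_start = 0, t_end = schedule$duration,
                               clock_id = "receiver") {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  onsets <- as.numeric(onsets)
  if (length(onsets) > 1L) {
    if (any(diff(onsets) < 0)) stop("`onsets` must be sorted", call. = FALSE)
    if (any(diff(onsets) < schedule$pulse_width)) {
      stop("overlapping pulses: onsets closer than `pulse_width`", call. = FALSE)
    }
  }
  if (!is.finite(rate) || rate <= 0) stop("`rate` must be positive", call. = FALSE)
  n <- round((t_end - t_start) * rate)
  t <- t_start + (seq_len(n) - 1) / rate
  v <- numeric(n)
  if (length(onsets)) {
    idx <- findInterval(t, onsets)
    inside <- idx > 0L
    inside[inside] <- t[inside] < onsets[idx[inside]] + schedule$pulse_width
    v[inside] <- schedule$amplitude
  }
  sampled_stream("audio", clock_id, rate, t, v)
}
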