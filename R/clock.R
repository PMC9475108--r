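#' Device clock model
#'
#' Maps true (reference) time to a device's local clock reading.  The mapping
#' is
#' \deqn{local(t) = t + o + d\,t + a\,(1 - e^{-t/\tau}) + \epsilon,}
#' with initial offset \eqn{o}, linear drift rate \eqn{d} (s/s, ppm scale),
#' a saturating drift term of amplitude \eqn{a} and timescale \eqn{\tau}
#' (clock rate differences that settle as a device warms up), and optional
#' per-read Gaussian timestamp noise \eqn{\epsilon}.  With all parameters
#' zero the clock is the identity.
#'
#' @param initial_offset Clock offset at t = 0, seconds.
#' @param drift_rate Linear drift rate in s/s; physical crystal drifts are
#'   on the ppm scale (|d| well below 1e-3, which keeps the mapping strictly
#'   increasing).
#' @param saturating_amplitude Amplitude of the saturating drift term,
#'   seconds.
#' @param saturating_timescale Timescale of the saturating term, seconds.
#' @param timestamp_noise_sd Standard deviation of per-read timestamp noise,
#'   seconds.
#'
#' @return An object of class `clock_model`.
#' @seealso [clock_time()], [local_timestamps()]
#' @export
#' @examples
#' clk <- clock_model(initial_offset = 0.5, drift_rate = 5e-5)
#' clock_time(clk, 100)  # 100 + 0.5 + 5e-3
clock_model <- function(initial_offset = 0, drift_rate = 0,
                        saturating_amplitude = 0, saturating_timescale = 1000,
                        timestamp_noise_sd = 0) {
  vals <- c(initial_offset, drift_rate, saturating_amplitude,
            saturating_timescale, timestamp_noise_sd)
  if (any(!is.finite(vals))) stop("clock parameters must be finite", call. = FALSE)
  if (abs(drift_rate) >= 1e-3) {
    stop("`drift_rate` must satisfy |drift_rate| < 1e-3 (ppm scale)", call. = FALSE)
  }
  if (saturating_timescale <= 0) {
    stop("`saturating_timescale` must be positive", call. = FALSE)
  }
  if (timestamp_noise_sd < 0) {
    stop("`timestamp_noise_sd` must be non-negative", call. = FALSE)
  }
  structure(
    list(initial_offset = initial_offset, drift_rate = drift_rate,
         saturating_amplitude = saturating_amplitude,
         saturating_timescale = saturating_timescale,
         timestamp_noise_sd = timestamp_noise_sd),
    class = "clock_model"
  )
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf(
    "<clock_model> offset %g s, drift %g s/s, saturating %g s / %g s, noise sd %g s\n",
    x$initial_offset, x$drift_rate, x$saturating_amplitude,
    x$saturating_timescale, x$timestamp_noise_sd))
  invisible(x)
}

#' Deterministic clock mapping
#'
#' Evaluates the noiseless part of a [clock_model()] mapping at true times
#' `t`.
#'
#' @param clock A [clock_model()].
#' @param t Numeric vector of true times, seconds.
#' @return Local clock readings, same length as `t`.
#' @export
clock_time <- function(clock, t) {
  stopifnot(inherits(clock, "clock_model"))
  t + clock$initial_offset + clock$drift_rate * t +
    clock$saturating_amplitude * (1 - exp(-t / clock$saturating_timescale))
}

#' Read local timestamps for a series of true times
#'
#' Applies the clock mapping and adds independent per-read timestamp noise.
#' Deterministic under a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @param clock A [clock_model()].
#' @param true_times Sorted numeric vector of true times, seconds.
#' @param seed Integer seed for the timestamp-noise draws.
#' @return Numeric vector of local timestamps.
#' @export
local_timestamps <- function(clock, true_times, seed = 1L) {
  stopifnot(inherits(clock, "clock_model"))
  true_times <- as.numeric(true_times)
  if (length(true_times) > 1L && any(diff(true_times) < 0)) {
    stop("`true_times` must be sorted", call. = FALSE)
  }
  ts <- clock_time(clock, true_times)
  if (clock$timestamp_noise_sd > 0 && length(ts)) {
    noise <- with_substream(seed, "clock_read_noise",
                            stats::rnorm(length(ts), 0, clock$timestamp_noise_sd))
    ts <- ts + noise
  }
  ts
}

#' Protocol for periodic clock-offset measurements
#'
#' Configuration of the NTP-style offset measurement protocol: one
#' measurement of the momentary receiver-minus-sender clock offset every
#' `interval` seconds, with Gaussian measurement noise and sporadic outliers
#' (as produced by occasional asymmetric network round trips).
#'
#' @param interval Measurement interval, seconds (default 5).
#' @param measurement_noise_sd Sd of the measurement noise, seconds.
#' @param outlier_probability Probability that a measurement is replaced by
#'   an outlier.
#' @param outlier_magnitude Magnitude of outliers, seconds (applied with a
#'   random sign).
#'
#' @return An object of class `offset_protocol_config`.
#' @export
offset_protocol_config <- function(interval = 5, measurement_noise_sd = 1e-4,
                                   outlier_probability = 0,
                                   outlier_magnitude = 0.15) {
  if (!is.finite(interval) || interval <= 0) {
    stop("`interval` must be positive", call. = FALSE)
  }
  stopifnot(measurement_noise_sd >= 0,
            outlier_probability >= 0, outlier_probability <= 1,
            outlier_magnitude >= 0)
  structure(
    list(interval = interval, measurement_noise_sd = measurement_noise_sd,
         outlier_probability = outlier_probability,
         outlier_magnitude = outlier_magnitude),
    class = "offset_protocol_config"
  )
}

#' Measure clock-correction offsets between two clocks
#'
#' Simulates the periodic offset protocol between a receiver and a sender
#' clock over a recording of the given duration.  Measurements are taken on
#' a regular grid starting at t = 0 (true time), giving
#' `floor(duration / interval) + 1` measurements.  Each measured value is the
#' momentary receiver-minus-sender clock difference plus measurement noise;
#' with probability `outlier_probability` the measurement is displaced by
#' `outlier_magnitude` with a random sign.
#'
#' @param receiver_clock,sender_clock [clock_model()] objects.
#' @param protocol An [offset_protocol_config()].
#' @param duration Recording duration, seconds (> 0).
#' @param seed Integer seed.
#' @param receiver_clock_id,sender_clock_id Clock identifiers recorded in the
#'   result.
#' @return A [clock_offset_series()]; `times` are receiver-clock readings.
#' @export
measure_clock_offsets <- function(receiver_clock, sender_clock, protocol,
                                  duration, seed = 1L,
                                  receiver_clock_id = "receiver",
                                  sender_clock_id = "sender") {
  stopifnot(inherits(receiver_clock, "clock_model"),
            inherits(sender_clock, "clock_model"),
            inherits(protocol, "offset_protocol_config"))
  if (!is.finite(duration) || duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  n <- floor(duration / protocol$interval) + 1L
  t_true <- (seq_len(n) - 1L) * protocol$interval
  recv <- clock_time(receiver_clock, t_true)
  send <- clock_time(sender_clock, t_true)
  measured <- recv - send
  if (length(measured)) {
    noise <- with_substream(seed, "protocol_noise", {
      e <- stats::rnorm(n, 0, protocol$measurement_noise_sd)
      out <- stats::runif(n) < protocol$outlier_probability
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      list(e = e, out = out, sgn = sgn)
    })
    measured <- measured + noise$e
    measured[noise$out] <- measured[noise$out] +
      noise$sgn[noise$out] * protocol$outlier_magnitude
  }
  clock_offset_series(receiver_clock_id, sender_clock_id, recv, measured)
}
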