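#' Sender (stimulus playback) configuration
#'
#' Parameters of the simulated stimulus sender: a device that plays the
#' rectangular test stimulus through its audio output while emitting a
#' software event marker for every pulse.  The physical playback lags the
#' marker by `playout_latency` plus a per-trial Gaussian jitter (buffering in
#' the audio path).  The default lag of 32.7 ms matches the block-size /
#' sampling-rate combination of the portable hearing device the simulator
#' emulates.
#'
#' @param audio_rate Audio sampling rate, Hz (default 16000).
#' @param playout_latency Marker-to-playback delay, seconds (default
#'   0.0327).  Negative values are permitted (a device could stamp markers
#'   after playback started).
#' @param playout_jitter_sd Per-trial sd of the playback delay, seconds.
#' @param marker_label Label prefix for emitted markers.
#'
#' @return An object of class `sender_config`.
#' @export
sender_config <- function(audio_rate = 16000, playout_latency = 0.0327,
                          playout_jitter_sd = 8e-5,
                          marker_label = "pulse") {
  vals <- c(audio_rate, playout_latency, playout_jitter_sd)
  if (any(!is.finite(vals))) stop("sender parameters must be finite", call. = FALSE)
  if (audio_rate <= 0) stop("`audio_rate` must be positive", call. = FALSE)
  if (playout_jitter_sd < 0) stop("`playout_jitter_sd` must be non-negative", call. = FALSE)
  structure(
    list(audio_rate = audio_rate, playout_latency = playout_latency,
         playout_jitter_sd = playout_jitter_sd, marker_label = marker_label),
    class = "sender_config"
  )
}

#' EEG acquisition chain configuration
#'
#' Parameters of the simulated EEG system: an amplifier sampling an analog
#' input at `eeg_rate` whose samples are timestamped by a counter-based
#' scheme on the streaming device, delivered over a wireless link in chunks.
#'
#' The chain models four timing effects observed in wireless mobile EEG
#' systems:
#' \itemize{
#'   \item a constant acquisition delay (`fixed_delay`) plus a constant
#'     timestamp correction (`timestamp_correction_bias`, negative when the
#'     streaming software overcorrects for the wireless link latency --
#'     which makes measured lags negative);
#'   \item a *stochastic sampling schedule*: timestamps deviate from the
#'     nominal grid by an autocorrelated (AR(1)) timing-offset process with
#'     marginal sd `sampling_schedule_jitter_sd` and correlation timescale
#'     `schedule_jitter_timescale`.  OS/driver scheduling errors are
#'     block-coherent, so neighbouring samples share almost the same offset
#'     while offsets a second apart are essentially independent;
#'   \item *internal drift* of the ADC sampling clock relative to the
#'     counter used for timestamping (`internal_drift_rate` plus a
#'     saturating term), which produces the slow latency drift that clock
#'     correction between devices cannot remove because it is internal to
#'     the EEG system;
#'   \item an anti-alias front end, modeled as a boxcar (moving-average)
#'     filter of half-width `antialias_halfwidth` applied to the analog
#'     signal before sampling.  The default half-width of one sample period
#'     turns a vertical edge into a linear ramp spanning two sample periods,
#'     so that linearly interpolated threshold crossings recover edge times
#'     without sampling-phase bias.
#' }
#' Chunked delivery (`chunk_period`) affects the order in which samples
#' become available, never their timestamps.
#'
#' @param eeg_rate EEG sampling rate, Hz (default 250).
#' @param fixed_delay Constant acquisition delay, seconds.
#' @param sampling_schedule_jitter_sd Marginal sd of the stochastic-schedule
#'   timing offset, seconds (default 3e-3).
#' @param schedule_jitter_timescale Correlation timescale of the schedule
#'   offset process, seconds (default 0.2).
#' @param chunk_period Period of chunked delivery, seconds (must be at least
#'   one sample period).
#' @param timestamp_correction_bias Constant timestamp correction applied by
#'   the streaming software, seconds; may be negative (overcorrection).
#' @param additive_noise_sd Sd of additive noise on sample values, signal
#'   units.
#' @param internal_drift_rate Linear drift of the sampling clock relative to
#'   the timestamp counter, s/s.
#' @param internal_drift_amplitude,internal_drift_timescale Saturating
#'   component of the internal drift (seconds; settles with the given
#'   timescale), reproducing latency curves that rise and then flatten over
#'   hours.
#' @param antialias_halfwidth Half-width of the boxcar anti-alias filter,
#'   seconds; `NULL` defaults to one sample period, 0 disables filtering.
#'
#' @return An object of class `eeg_chain_config`.
#' @export
eeg_chain_config <- function(eeg_rate = 250, fixed_delay = 0,
                             sampling_schedule_jitter_sd = 3e-3,
                             schedule_jitter_timescale = 0.2,
                             chunk_period = 0.02,
                             timestamp_correction_bias = 0,
                             additive_noise_sd = 0,
                             internal_drift_rate = 0,
                             internal_drift_amplitude = 0,
                             internal_drift_timescale = 2000,
                             antialias_halfwidth = NULL) {
  if (!is.finite(eeg_rate) || eeg_rate <= 0) {
    stop("`eeg_rate` must be positive", call. = FALSE)
  }
  if (is.null(antialias_halfwidth)) antialias_halfwidth <- 1 / eeg_rate
  vals <- c(fixed_delay, sampling_schedule_jitter_sd, schedule_jitter_timescale,
            chunk_period, timestamp_correction_bias, additive_noise_sd,
            internal_drift_rate, internal_drift_amplitude,
            internal_drift_timescale, antialias_halfwidth)
  if (any(!is.finite(vals))) stop("EEG chain parameters must be finite", call. = FALSE)
  if (chunk_period < 1 / eeg_rate) {
    stop("`chunk_period` must be at least one sample period", call. = FALSE)
  }
  stopifnot(sampling_schedule_jitter_sd >= 0, schedule_jitter_timescale > 0,
            additive_noise_sd >= 0, internal_drift_timescale > 0,
            antialias_halfwidth >= 0)
  structure(
    list(eeg_rate = eeg_rate, fixed_delay = fixed_delay,
         sampling_schedule_jitter_sd = sampling_schedule_jitter_sd,
         schedule_jitter_timescale = schedule_jitter_timescale,
         chunk_period = chunk_period,
         timestamp_correction_bias = timestamp_correction_bias,
         additive_noise_sd = additive_noise_sd,
         internal_drift_rate = internal_drift_rate,
         internal_drift_amplitude = internal_drift_amplitude,
         internal_drift_timescale = internal_drift_timescale,
         antialias_halfwidth = antialias_halfwidth),
    class = "eeg_chain_config"
  )
}

# Internal ADC-vs-counter drift at counter time t (seconds of extra latency).
eeg_internal_drift <- function(config, t) {
  config$internal_drift_rate * t +
    config$internal_drift_amplitude *
      (1 - exp(-pmax(t, 0) / config$internal_drift_timescale))
}

#' Simulate the stimulus sender
#'
#' Generates the sender's two outputs for one session: the marker stream
#' (timestamps read from the sender's clock at the true onset times) and the
#' physical audio signal, in which each pulse is played
#' `playout_latency + jitter` after its marker's true time.  The per-trial
#' marker-to-playback delays are returned as ground truth.
#'
#' @param config A [sender_config()].
#' @param schedule A [stimulus_schedule()].
#' @param clock [clock_model()] of the sender device.
#' @param seed Integer seed.
#' @param t_start,t_end Span of the rendered audio grid; defaults add no
#'   padding.  Supplying a span wider than `[0, duration]` gives the
#'   downstream pipeline room for epoch windows around the first and last
#'   trials.
#' @param sender_clock_id,receiver_clock_id Clock identifiers for the marker
#'   stream and the (reference-timeline) audio signal.
#' @return A list with elements `audio` ([sampled_stream()]), `markers`
#'   ([marker_stream()]), `onsets` (true onset times) and `playout_delay`
#'   (per-trial true marker-to-edge latency).
#' @export
simulate_sender <- function(config, schedule, clock = clock_model(),
                            seed = 1L, t_start = 0,
                            t_end = schedule$duration,
                            sender_clock_id = "sender",
                            receiver_clock_id = "receiver") {
  stopifnot(inherits(config, "sender_config"),
            inherits(schedule, "stimulus_schedule"),
            inherits(clock, "clock_model"))
  onsets <- generate_stimulus_onsets(schedule)
  n <- length(onsets)
  delays <- rep(config$playout_latency, n)
  if (config$playout_jitter_sd > 0 && n) {
    delays <- delays + with_substream(seed, "playout",
                                      stats::rnorm(n, 0, config$playout_jitter_sd))
  }
  audio_onsets <- onsets + delays
  audio <- render_square_wave(audio_onsets, schedule, config$audio_rate,
                              t_start = t_start, t_end = t_end,
                              clock_id = receiver_clock_id)
  marker_ts <- local_timestamps(clock, onsets, seed = derive_seed(seed, "marker_clock"))
  markers <- marker_stream("audio_markers", sender_clock_id, marker_ts,
                           if (n) paste0(config$marker_label, "_", seq_len(n))
                           else character(0))
  list(audio = audio, markers = markers, onsets = onsets,
       playout_delay = delays)
}

# Boxcar (moving average) smoothing of a regularly sampled signal via
# cumulative sums; edges use shrinking windows so the output length matches.
boxcar_smooth <- function(v, halfwidth_samples) {
  m <- as.integer(halfwidth_samples)
  if (m <= 0L || length(v) == 0L) return(v)
  n <- length(v)
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - m, 1L)
  hi <- pmin(seq_len(n) + m, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Simulate the EEG acquisition chain
#'
#' Converts an analog input signal into an EEG data stream the way a
#' wireless, counter-timestamped EEG system does.  The analog signal is
#' low-pass filtered by the anti-alias front end, sampled at counter times
#' `n / eeg_rate` warped by the chain's internal ADC drift, and timestamped
#' as
#' `clock_local(t_n) + fixed_delay + timestamp_correction_bias + schedule offset`,
#' where the schedule offset is the autocorrelated stochastic-schedule
#' process described in [eeg_chain_config()].  Additive Gaussian noise is
#' applied to the sample values.  Chunked delivery groups samples into
#' bursts (recorded in the `chunk` attribute) but never alters timestamps.
#'
#' @param analog A [sampled_stream()] holding the analog input on a regular
#'   grid (reference timeline).
#' @param config An [eeg_chain_config()].
#' @param clock [clock_model()] of the device that timestamps the stream.
#' @param seed Integer seed.
#' @param eeg_clock_id Clock identifier of the produced stream.
#' @return A [sampled_stream()] at `eeg_rate` spanning the analog input.
#' @export
simulate_eeg_acquisition <- function(analog, config, clock = clock_model(),
                                     seed = 1L, eeg_clock_id = "eeg") {
  stopifnot(inherits(analog, "sampled_stream"),
            inherits(config, "eeg_chain_config"),
            inherits(clock, "clock_model"))
  if (config$eeg_rate > analog$nominal_rate) {
    stop("`eeg_rate` must not exceed the analog sampling rate", call. = FALSE)
  }
  at <- analog$timestamps
  if (length(at) < 2L) stop("analog stream needs at least 2 samples", call. = FALSE)
  dt_analog <- 1 / analog$nominal_rate

  hw <- round(config$antialias_halfwidth * analog$nominal_rate)
  av <- boxcar_smooth(analog$values, hw)

  # counter times on the nominal grid spanning the analog input
  t0 <- at[1L]
  t1 <- at[length(at)]
  nn <- floor((t1 - t0) * config$eeg_rate) + 1L
  t_n <- t0 + (seq_len(nn) - 1L) / config$eeg_rate

  # true sampling times: counter time minus accumulated internal drift
  w_n <- t_n - eeg_internal_drift(config, t_n - t0)

  # sample the smoothed analog signal at the true sampling times
  fi <- (w_n - t0) / dt_analog
  i0 <- pmin(pmax(floor(fi), 0), length(av) - 2L)
  frac <- fi - i0
  vals <- av[i0 + 1L] * (1 - frac) + av[i0 + 2L] * frac

  ts <- local_timestamps(clock, t_n, seed = derive_seed(seed, "eeg_clock")) +
    config$fixed_delay + config$timestamp_correction_bias

  if (config$sampling_schedule_jitter_sd > 0) {
    rho <- exp(-(1 / config$eeg_rate) / config$schedule_jitter_timescale)
    delta <- with_substream(seed, "schedule", {
      z <- stats::rnorm(nn)
      x <- c(z[1L], sqrt(1 - rho^2) * z[-1L])
      d <- as.numeric(stats::filter(x, rho, method = "recursive"))
      d * config$sampling_schedule_jitter_sd
    })
    ts <- ts + delta
  }
  if (config$additive_noise_sd > 0) {
    vals <- vals + with_substream(seed, "value_noise",
                                  stats::rnorm(nn, 0, config$additive_noise_sd))
  }
  if (any(diff(ts) < 0)) {
    stop(paste("EEG timestamps are not monotone under this configuration;",
               "reduce `sampling_schedule_jitter_sd` or increase",
               "`schedule_jitter_timescale`"), call. = FALSE)
  }
  out <- sampled_stream("eeg", eeg_clock_id, config$eeg_rate, ts, vals)
  attr(out, "chunk") <- floor((t_n - t0) / config$chunk_period)
  out
}

#' Session configuration
#'
#' Collects all component configurations of a simulated recording session.
#' Defaults reproduce the study conditions of the emulated setup: 60 ms
#' pulses at 1 Hz for 15 min, 16 kHz audio with a 32.7 ms playout lag and
#' sub-0.1 ms playout jitter, a 250 Hz EEG chain with about 3 ms
#' stochastic-schedule jitter, and clock-offset measurements every 5 s.
#'
#' @param schedule A [stimulus_schedule()].
#' @param sender A [sender_config()].
#' @param eeg_chain An [eeg_chain_config()].
#' @param protocol An [offset_protocol_config()].
#' @param sender_clock,eeg_clock,receiver_clock [clock_model()] objects for
#'   the three devices.  The receiver clock defines the common timeline and
#'   defaults to the identity.
#' @param pad Lead-in/lead-out padding of the rendered streams, seconds
#'   (default 0.5); gives the analysis pipeline complete epoch windows
#'   around the first and last trials.
#' @return An object of class `session_config`.
#' @export
session_config <- function(schedule = stimulus_schedule(),
                           sender = sender_config(),
                           eeg_chain = eeg_chain_config(),
                           protocol = offset_protocol_config(),
                           sender_clock = clock_model(),
                           eeg_clock = clock_model(),
                           receiver_clock = clock_model(),
                           pad = 0.5) {
  stopifnot(inherits(schedule, "stimulus_schedule"),
            inherits(sender, "sender_config"),
            inherits(eeg_chain, "eeg_chain_config"),
            inherits(protocol, "offset_protocol_config"),
            inherits(sender_clock, "clock_model"),
            inherits(eeg_clock, "clock_model"),
            inherits(receiver_clock, "clock_model"),
            pad >= 0)
  if (eeg_chain$eeg_rate >= sender$audio_rate) {
    stop("`eeg_rate` must be below the sender's `audio_rate`", call. = FALSE)
  }
  structure(
    list(schedule = schedule, sender = sender, eeg_chain = eeg_chain,
         protocol = protocol, sender_clock = sender_clock,
         eeg_clock = eeg_clock, receiver_clock = receiver_clock, pad = pad),
    class = "session_config"
  )
}

#' Simulate a complete recording session
#'
#' Composes the full signal flow of the emulated setup: the sender plays the
#' pulse stimulus and emits event markers; the physical audio signal is fed
#' into the EEG chain; the receiver measures clock-correction offsets
#' against the sender and EEG clocks every `interval` seconds.  The result
#' is an internally consistent [recording_bundle()] with known ground truth.
#' Identical `(config, seed)` pairs yield identical bundles.
#'
#' @param config A [session_config()].
#' @param seed Integer session seed.
#' @return A [recording_bundle()].
#' @export
#' @examples
#' cfg <- session_config(schedule = stimulus_schedule(duration = 20))
#' b <- simulate_session(cfg, seed = 1)
#' b
simulate_session <- function(config, seed = 1L) {
  stopifnot(inherits(config, "session_config"))
  dur <- config$schedule$duration
  snd <- simulate_sender(config$sender, config$schedule,
                         clock = config$sender_clock,
                         seed = derive_seed(seed, "sender"),
                         t_start = -config$pad, t_end = dur + config$pad)
  eeg <- simulate_eeg_acquisition(snd$audio, config$eeg_chain,
                                  clock = config$eeg_clock,
                                  seed = derive_seed(seed, "eeg"))
  off_dur <- dur + config$pad
  offsets <- list(
    sender = measure_clock_offsets(config$receiver_clock, config$sender_clock,
                                   config$protocol, off_dur,
                                   seed = derive_seed(seed, "protocol_sender"),
                                   receiver_clock_id = "receiver",
                                   sender_clock_id = "sender"),
    eeg = measure_clock_offsets(config$receiver_clock, config$eeg_clock,
                                config$protocol, off_dur,
                                seed = derive_seed(seed, "protocol_eeg"),
                                receiver_clock_id = "receiver",
                                sender_clock_id = "eeg")
  )
  gt <- list(
    onsets = snd$onsets,
    playout_delay = snd$playout_delay,
    eeg_fixed_latency = config$eeg_chain$fixed_delay +
      config$eeg_chain$timestamp_correction_bias,
    eeg_drift_at_trials = eeg_internal_drift(config$eeg_chain,
                                             snd$onsets + config$pad),
    sender_clock = unclass(config$sender_clock),
    eeg_clock = unclass(config$eeg_clock)
  )
  recording_bundle(audio_stream = snd$audio, marker_stream = snd$markers,
                   eeg_stream = eeg, offsets = offsets, ground_truth = gt,
                   config = config, seed = seed)
}
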