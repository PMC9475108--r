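#' Per-trial latency series
#'
#' The unit of all downstream timing statistics: one latency
#' \eqn{\Delta t_n} per trial, with the trial times on the common timeline.
#' The sign convention throughout is
#' \eqn{\Delta t = t_\mathrm{observed} - t_\mathrm{reference}}: positive
#' when the observed event (signal edge or half-maximum crossing) occurs
#' after the reference event (marker or analog input edge).
#'
#' @param scenario One of `"I"`, `"II"`, `"III"`.
#' @param trial_times Trial times, seconds (common timeline).
#' @param latencies Per-trial latencies, seconds; same length.
#' @param session_id Session identifier.
#' @param dropped Named counts of excluded trials (optional bookkeeping).
#' @return An object of class `latency_series`.
#' @export
latency_series <- function(scenario, trial_times, latencies,
                           session_id = "session", dropped = c()) {
  scenario <- match.arg(scenario, c("I", "II", "III"))
  trial_times <- as.numeric(trial_times)
  latencies <- as.numeric(latencies)
  if (length(trial_times) != length(latencies)) {
    stop("`trial_times` and `latencies` must have equal length", call. = FALSE)
  }
  structure(
    list(scenario = scenario, trial_times = trial_times,
         latencies = latencies, session_id = session_id, dropped = dropped),
    class = "latency_series"
  )
}

#' @export
print.latency_series <- function(x, ...) {
  cat(sprintf("<latency_series> scenario %s, %d trials", x$scenario,
              length(x$latencies)))
  if (length(x$latencies) >= 2L) {
    cat(sprintf(": lag %.3f ms, jitter %.3f ms", 1e3 * lag(x), 1e3 * jitter(x)))
  }
  cat("\n")
  invisible(x)
}

as_latencies <- function(x) {
  if (inherits(x, "latency_series")) x$latencies else as.numeric(x)
}

#' Session lag (mean latency)
#'
#' The lag of a timing-test session is the arithmetic mean of its per-trial
#' latencies, \eqn{\mathrm{lag} = \frac{1}{N}\sum_{n=1}^N \Delta t_n}.
#'
#' Note this masks `stats::lag()`; call `stats::lag()` explicitly for the
#' time-series shift operator.
#'
#' @param series A [latency_series()] or a numeric vector of latencies
#'   (seconds); must be non-empty.
#' @return The lag in seconds.
#' @export
lag <- function(series) {
  x <- as_latencies(series)
  if (length(x) == 0L) stop("cannot compute lag of an empty series", call. = FALSE)
  mean(x)
}

#' Session jitter (latency standard deviation)
#'
#' The jitter of a timing-test session is the sample standard deviation of
#' its per-trial latencies,
#' \eqn{\mathrm{jitter} = \sqrt{\frac{1}{N-1}\sum_{n=1}^N
#' |\Delta t_n - \mathrm{lag}|^2}}.
#'
#' Note this masks `base::jitter()`; call `base::jitter()` explicitly to add
#' noise to a vector.
#'
#' @param series A [latency_series()] or numeric vector with at least 2
#'   latencies (seconds).
#' @return The jitter in seconds (non-negative).
#' @export
jitter <- function(series) {
  x <- as_latencies(series)
  if (length(x) < 2L) {
    stop("jitter requires at least 2 latencies", call. = FALSE)
  }
  stats::sd(x)
}

#' Across-session range of a timing metric
#'
#' The spread of lag (or jitter) across all timing-test sessions of one
#' condition: the maximum minus the minimum value.
#'
#' @param values Non-empty numeric vector of per-session lags or jitters.
#' @return `max(values) - min(values)` (non-negative).
#' @export
#' @examples
#' across_session_range(c(32.69, 32.76, 32.81, 32.68, 32.67))  # 0.14
across_session_range <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop("cannot compute a range over zero sessions", call. = FALSE)
  }
  max(values) - min(values)
}

#' Summarize one timing-test session
#'
#' @param series A [latency_series()].
#' @param duration_class `"15min"`, `"3h"`, or other label.
#' @return A `timing_summary` (also a one-row data frame) with lag, jitter
#'   (seconds; jitter is `NA` for fewer than 2 trials), trial count, session
#'   id, scenario and duration class.
#' @export
timing_summary <- function(series, duration_class = NA_character_) {
  stopifnot(inherits(series, "latency_series"))
  n <- length(series$latencies)
  out <- data.frame(
    session_id = series$session_id, scenario = series$scenario,
    duration_class = duration_class, n = n,
    lag = if (n >= 1L) lag(series) else NA_real_,
    jitter = if (n >= 2L) jitter(series) else NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("timing_summary", class(out))
  out
}

#' Summarize a condition across sessions
#'
#' Combines the per-session summaries of one condition (same scenario and
#' duration) and computes the across-session range of lag and jitter.
#'
#' @param summaries A list of [timing_summary()] rows (or a data frame of
#'   them).
#' @return A `condition_summary`: list with the stacked `sessions` table and
#'   `delta_r_lag` / `delta_r_jitter` in seconds.
#' @export
condition_summary <- function(summaries) {
  if (inherits(summaries, "data.frame")) sessions <- summaries
  else sessions <- do.call(rbind, summaries)
  if (is.null(sessions) || nrow(sessions) == 0L) {
    stop("no sessions to summarize", call. = FALSE)
  }
  structure(
    list(sessions = sessions,
         delta_r_lag = across_session_range(sessions$lag),
         delta_r_jitter = if (all(is.na(sessions$jitter))) NA_real_
                          else across_session_range(sessions$jitter[!is.na(sessions$jitter)])),
    class = "condition_summary"
  )
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> %d sessions\n", nrow(x$sessions)))
  print(as.data.frame(x$sessions))
  cat(sprintf("  delta-R lag: %.4g ms, delta-R jitter: %.4g ms\n",
              1e3 * x$delta_r_lag, 1e3 * x$delta_r_jitter))
  invisible(x)
}

#' Scenario I latencies: event markers vs. audio playback
#'
#' Per-trial latency between each software event marker and the rising edge
#' of the corresponding pulse in the physical playback signal:
#' \eqn{\Delta t_n = t_\mathrm{edge} - t_\mathrm{marker}} (positive when
#' playback follows the marker).  Both inputs must be on a common timeline.
#'
#' @param markers A [marker_stream()].
#' @param audio A [sampled_stream()] holding the playback signal.
#' @param threshold_fraction,min_separation Edge-detection parameters, see
#'   [detect_rising_edges()].
#' @param max_abs_offset Pairing window, see [pair_events()].
#' @param session_id Session identifier for the result.
#' @return A [latency_series()] (scenario `"I"`).
#' @export
latencies_scenario1 <- function(markers, audio, threshold_fraction = 0.5,
                                min_separation = 0.03, max_abs_offset = 0.4,
                                session_id = "session") {
  stopifnot(inherits(markers, "marker_stream"),
            inherits(audio, "sampled_stream"))
  edges <- detect_rising_edges(audio, threshold_fraction, min_separation)
  pairs <- pair_events(markers$timestamps, edges, max_abs_offset)
  if (nrow(pairs) == 0L) {
    stop("no marker/edge pairs found within the pairing window", call. = FALSE)
  }
  latency_series("I", pairs$t_ref, pairs$t_obs - pairs$t_ref,
                 session_id = session_id, dropped = attr(pairs, "dropped"))
}

#' Scenario II latencies: EEG stream vs. analog input
#'
#' Per-trial latency between the rising edges in the (timeline-mapped) EEG
#' data stream and the rising edges of the analog test signal fed into the
#' EEG system: \eqn{\Delta t_n = t_\mathrm{edge,EEG} -
#' t_\mathrm{edge,reference}}.  Negative values indicate that the EEG
#' system's timestamps place the edge *before* the physical input edge (a
#' timestamp overcorrection).
#'
#' @param eeg A [sampled_stream()], already mapped into the common timeline.
#' @param reference A [sampled_stream()] holding the analog input signal.
#' @inheritParams latencies_scenario1
#' @return A [latency_series()] (scenario `"II"`).
#' @export
latencies_scenario2 <- function(eeg, reference, threshold_fraction = 0.5,
                                min_separation = 0.03, max_abs_offset = 0.4,
                                session_id = "session") {
  stopifnot(inherits(eeg, "sampled_stream"),
            inherits(reference, "sampled_stream"))
  eeg_edges <- detect_rising_edges(eeg, threshold_fraction, min_separation)
  ref_edges <- detect_rising_edges(reference, threshold_fraction, min_separation)
  pairs <- pair_events(ref_edges, eeg_edges, max_abs_offset)
  if (nrow(pairs) == 0L) {
    stop("no EEG/reference edge pairs found within the pairing window",
         call. = FALSE)
  }
  latency_series("II", pairs$t_ref, pairs$t_obs - pairs$t_ref,
                 session_id = session_id, dropped = attr(pairs, "dropped"))
}

#' Scenario III latencies: full in-the-loop pipeline
#'
#' Per-trial latency of the complete setup, computed the way an
#' event-related-potential analysis would see it:
#' \enumerate{
#'   \item map the marker stream and the EEG stream into the receiver's
#'     common timeline (skipped with `sync_method = "none"`, which exposes
#'     uncorrected clock drift);
#'   \item upsample the EEG stream to the audio rate by linear
#'     interpolation;
#'   \item epoch the EEG from -100 to +150 ms around each marker;
#'   \item baseline-correct each epoch by subtracting its mean over
#'     -100 to -50 ms;
#'   \item average the epochs and set the threshold to half the maximum of
#'     the trial-averaged response;
#'   \item per trial, take \eqn{\Delta t_n} as the time (relative to the
#'     marker) of the first upward crossing of that threshold, linearly
#'     interpolated on the upsampled grid.
#' }
#' Trials whose epoch window falls outside the recording, or that never
#' cross the threshold, are excluded and counted in `dropped`.
#'
#' @param eeg A [sampled_stream()] (EEG clock or already mapped).
#' @param markers A [marker_stream()] (sender clock or already mapped).
#' @param offsets Named list of [clock_offset_series()] keyed by sender
#'   clock id (as in a [recording_bundle()]), or a single series; ignored
#'   when `sync_method = "none"`.
#' @param sync_method `"most-recent"`, `"robust-linear"`, or `"none"`.
#' @param window Trailing-window size for the robust method.
#' @param target_rate Upsampling target, Hz (the audio rate; default 16000).
#' @param epoch_window Epoch limits relative to the marker, seconds.
#' @param baseline_window Baseline limits relative to the marker, seconds
#'   (must lie within the epoch window).
#' @param session_id Session identifier.
#' @return A [latency_series()] (scenario `"III"`).
#' @export
latencies_scenario3 <- function(eeg, markers, offsets = NULL,
                                sync_method = c("most-recent", "robust-linear",
                                                "none"),
                                window = 10L, target_rate = 16000,
                                epoch_window = c(-0.100, 0.150),
                                baseline_window = c(-0.100, -0.050),
                                session_id = "session") {
  stopifnot(inherits(eeg, "sampled_stream"), inherits(markers, "marker_stream"))
  sync_method <- match.arg(sync_method)
  if (baseline_window[1L] < epoch_window[1L] ||
      baseline_window[2L] > epoch_window[2L]) {
    stop("`baseline_window` must lie within `epoch_window`", call. = FALSE)
  }
  if (sync_method != "none") {
    method <- timeline_map_method(
      if (sync_method == "most-recent") "most_recent_offset" else "robust_linear",
      window = window)
    eeg <- map_bundle_stream(eeg, offsets, method)
    markers <- map_bundle_stream(markers, offsets, method)
  }
  up <- upsample_to(eeg, target_rate)
  h <- 1 / target_rate
  t0 <- up$timestamps[1L]
  ngrid <- length(up$timestamps)
  len <- floor((epoch_window[2L] - epoch_window[1L]) / h) + 1L
  nb <- floor((baseline_window[2L] - baseline_window[1L]) / h) + 1L

  mts <- markers$timestamps
  start_idx <- ceiling((mts + epoch_window[1L] - t0) / h - 1e-9) + 1L
  ok <- start_idx >= 1L & (start_idx + len - 1L) <= ngrid
  n_outside <- sum(!ok)
  mts <- mts[ok]
  start_idx <- start_idx[ok]
  if (length(mts) == 0L) stop("no trials with complete epoch windows", call. = FALSE)

  idx <- outer(seq_len(len) - 1L, start_idx, "+")    # len x ntrial
  ep <- matrix(up$values[idx], nrow = len)
  base <- colMeans(ep[seq_len(nb), , drop = FALSE])
  ep <- sweep(ep, 2L, base)
  avg <- rowMeans(ep)
  peak <- max(avg)
  if (peak <= 0) stop("no threshold crossings: trial-averaged response has no positive peak",
                      call. = FALSE)
  thr <- 0.5 * peak

  lats <- rep(NA_real_, length(mts))
  for (i in seq_along(mts)) {
    v <- ep[, i]
    j <- which(v[-len] < thr & v[-1L] >= thr)
    if (length(j)) {
      j <- j[1L]
      tc <- (start_idx[i] + j - 2L) * h + t0 +
        (thr - v[j]) / (v[j + 1L] - v[j]) * h
      lats[i] <- tc - mts[i]
    }
  }
  crossed <- !is.na(lats)
  if (!any(crossed)) stop("no threshold crossings", call. = FALSE)
  latency_series("III", mts[crossed], lats[crossed], session_id = session_id,
                 dropped = c(no_crossing = sum(!crossed),
                             epoch_outside = n_outside))
}

# Map a stream using whichever series in `offsets` matches its clock;
# streams already on a receiver clock pass through unchanged.
map_bundle_stream <- function(stream, offsets, method) {
  if (inherits(offsets, "clock_offset_series")) offsets <- list(offsets)
  if (is.null(offsets) || length(offsets) == 0L) {
    stop("`offsets` is required unless sync_method = \"none\"", call. = FALSE)
  }
  receiver_ids <- unique(vapply(offsets, function(o) o$receiver_clock_id, ""))
  if (stream$clock_id %in% receiver_ids) return(stream)
  for (o in offsets) {
    if (identical(o$sender_clock_id, stream$clock_id)) {
      return(map_timeline(stream, o, method))
    }
  }
  stop(sprintf("no offset series found for clock '%s'", stream$clock_id),
       call. = FALSE)
}
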