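#' Detect rising edges in a sampled signal
#'
#' Finds the linearly interpolated times at which the signal crosses
#' `threshold_fraction * max(values)` upwards.  Crossings closer together
#' than `min_separation` are merged (debounce), keeping the first.  A
#' constant signal has no edges and yields an empty result.
#'
#' @param stream A non-empty [sampled_stream()].
#' @param threshold_fraction Fraction of the maximum value used as the
#'   threshold, in (0, 1); default 0.5 (half maximum).
#' @param min_separation Debounce interval, seconds; crossings within this
#'   distance of an accepted crossing are discarded.  Use half the pulse
#'   width for pulse-train signals (default 0.03 s for 60 ms pulses).
#' @return Numeric vector of edge times (same clock as the stream).
#' @export
detect_rising_edges <- function(stream, threshold_fraction = 0.5,
                                min_separation = 0.03) {
  stopifnot(inherits(stream, "sampled_stream"))
  if (length(stream$values) == 0L) stop("stream is empty", call. = FALSE)
  if (!is.finite(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1) {
    stop("`threshold_fraction` must be in (0, 1)", call. = FALSE)
  }
  v <- stream$values
  t <- stream$timestamps
  vmax <- max(v)
  if (vmax == min(v)) return(numeric(0))
  thr <- threshold_fraction * vmax
  i <- which(v[-length(v)] < thr & v[-1L] >= thr)
  if (length(i) == 0L) return(numeric(0))
  tc <- t[i] + (thr - v[i]) / (v[i + 1L] - v[i]) * (t[i + 1L] - t[i])
  if (length(tc) > 1L && min_separation > 0) {
    keep <- logical(length(tc))
    last <- -Inf
    for (k in seq_along(tc)) {
      if (tc[k] - last >= min_separation) {
        keep[k] <- TRUE
        last <- tc[k]
      }
    }
    tc <- tc[keep]
  }
  tc
}

#' Pair reference events with observed events
#'
#' One-to-one pairing of two sorted event-time lists: every reference event
#' is paired with the nearest observed event within `max_abs_offset`;
#' candidate pairs are accepted greedily in order of increasing absolute
#' offset (ties resolved toward the earlier observed event), so no event is
#' used twice.  Unpaired events on either side are dropped and counted in
#' the `dropped` attribute.
#'
#' @param reference_times,observed_times Sorted numeric vectors, seconds.
#' @param max_abs_offset Maximum |observed - reference| for a pair, seconds;
#'   keep this below half the stimulus period (default 0.4 s for 1 Hz
#'   trains).
#' @return A data frame with columns `t_ref` and `t_obs` (one row per pair,
#'   ordered by `t_ref`), and attribute `dropped` = c(reference, observed)
#'   counts of unpaired events.
#' @export
pair_events <- function(reference_times, observed_times, max_abs_offset = 0.4) {
  reference_times <- as.numeric(reference_times)
  observed_times <- as.numeric(observed_times)
  nr <- length(reference_times)
  no <- length(observed_times)
  if (nr == 0L || no == 0L) {
    out <- data.frame(t_ref = numeric(0), t_obs = numeric(0))
    attr(out, "dropped") <- c(reference = nr, observed = no)
    return(out)
  }
  # candidate pairs: every observed event within the window of each reference
  lo <- findInterval(reference_times - max_abs_offset, observed_times) + 1L
  hi <- findInterval(reference_times + max_abs_offset, observed_times)
  counts <- pmax(hi - lo + 1L, 0L)
  cand_r <- rep.int(seq_len(nr), counts)
  from <- lo
  from[counts == 0L] <- 1L
  cand_o <- sequence(counts, from = from)
  off <- abs(observed_times[cand_o] - reference_times[cand_r])
  ok <- off <= max_abs_offset
  cand_r <- cand_r[ok]; cand_o <- cand_o[ok]; off <- off[ok]
  # greedy matching by increasing |offset|; ties toward the earlier observed
  ord <- order(off, observed_times[cand_o], cand_r)
  used_r <- logical(nr)
  used_o <- logical(no)
  pr <- integer(0)
  po <- integer(0)
  for (k in ord) {
    r <- cand_r[k]; o <- cand_o[k]
    if (!used_r[r] && !used_o[o]) {
      used_r[r] <- TRUE
      used_o[o] <- TRUE
      pr <- c(pr, r)
      po <- c(po, o)
    }
  }
  o <- order(pr)
  out <- data.frame(t_ref = reference_times[pr[o]],
                    t_obs = observed_times[po[o]])
  attr(out, "dropped") <- c(reference = sum(!used_r), observed = sum(!used_o))
  out
}

#' Upsample a stream by linear interpolation
#'
#' Interpolates a sampled stream sample-wise onto a regular grid at
#' `target_rate` spanning the original timestamps.  Used to bring the EEG
#' stream to the audio rate before half-maximum latency extraction; for the
#' vertical-edged test signal, linear interpolation bounds the crossing-time
#' error by one source sample period.
#'
#' @param stream A [sampled_stream()] with at least 2 samples.
#' @param target_rate Target rate, Hz; must be at least the stream's nominal
#'   rate.
#' @return A [sampled_stream()] at `target_rate`.
#' @export
upsample_to <- function(stream, target_rate) {
  stopifnot(inherits(stream, "sampled_stream"))
  if (length(stream$timestamps) < 2L) {
    stop("need at least 2 samples to interpolate", call. = FALSE)
  }
  if (!is.finite(target_rate) || target_rate < stream$nominal_rate) {
    stop("`target_rate` must be at least the stream's nominal rate", call. = FALSE)
  }
  t0 <- stream$timestamps[1L]
  t1 <- stream$timestamps[length(stream$timestamps)]
  n <- floor((t1 - t0) * target_rate) + 1L
  grid <- t0 + (seq_len(n) - 1L) / target_rate
  vals <- stats::approx(stream$timestamps, stream$values, xout = grid,
                        method = "linear", rule = 2, ties = "ordered")$y
  sampled_stream(stream$name, stream$clock_id, target_rate, grid, vals)
}
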