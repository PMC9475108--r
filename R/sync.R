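#' Timeline mapping method
#'
#' @param kind Either `"most_recent_offset"` (each remote timestamp gains the
#'   last clock-correction offset measured at or before it; the default, and
#'   the conservative choice because it applies no smoothing) or
#'   `"robust_linear"` (each timestamp gains the value at that time of a
#'   robust Theil-Sen line fitted through a trailing window of offset
#'   measurements, which suppresses sporadic offset outliers).
#' @param window Number of trailing offset measurements used by the robust
#'   fit (>= 2).
#' @return An object of class `timeline_map_method`.
#' @seealso [map_timeline()]
#' @export
timeline_map_method <- function(kind = c("most_recent_offset", "robust_linear"),
                                window = 10L) {
  kind <- match.arg(kind)
  window <- as.integer(window)
  if (kind == "robust_linear" && window < 2L) {
    stop("`window` must be >= 2 for the robust linear method", call. = FALSE)
  }
  structure(list(kind = kind, window = window), class = "timeline_map_method")
}

#' Map a stream into the receiver's common timeline
#'
#' Adds the appropriate clock-correction offset to every timestamp of a
#' remotely recorded stream, producing timestamps on the receiver's clock.
#' With the `most_recent_offset` method each timestamp gains the last offset
#' measured at or before it; timestamps earlier than the first measurement
#' use the first measurement (nearest extrapolation, reported via the
#' `n_extrapolated` attribute).  With the `robust_linear` method each
#' timestamp gains the value of a Theil-Sen line through the trailing
#' `window` measurements, evaluated at that timestamp; before the window has
#' filled, all available measurements (at least 2) are used.
#'
#' @param stream A [sampled_stream()] or [marker_stream()] whose `clock_id`
#'   matches `offsets$sender_clock_id`.
#' @param offsets A non-empty [clock_offset_series()].
#' @param method A [timeline_map_method()] (default: most recent offset).
#' @return The stream with mapped timestamps, `clock_id` set to the
#'   receiver's, and attributes `n_extrapolated` (timestamps before the
#'   first measurement) recording the extrapolation count.
#' @export
map_timeline <- function(stream, offsets,
                         method = timeline_map_method()) {
  stopifnot(inherits(stream, "sampled_stream") || inherits(stream, "marker_stream"),
            inherits(offsets, "clock_offset_series"),
            inherits(method, "timeline_map_method"))
  if (length(offsets$times) == 0L) {
    stop("`offsets` is empty; cannot map timeline", call. = FALSE)
  }
  if (!identical(stream$clock_id, offsets$sender_clock_id)) {
    stop(sprintf("stream clock '%s' does not match offsets sender clock '%s'",
                 stream$clock_id, offsets$sender_clock_id), call. = FALSE)
  }
  ts <- stream$timestamps
  idx <- findInterval(ts, offsets$times)
  n_extrapolated <- sum(idx == 0L)
  idx[idx == 0L] <- 1L
  if (method$kind == "most_recent_offset" || length(offsets$times) == 1L) {
    shift <- offsets$offsets[idx]
  } else {
    shift <- numeric(length(ts))
    for (i in unique(idx)) {
      sel <- idx == i
      lo <- max(1L, i - method$window + 1L)
      xs <- offsets$times[lo:i]
      ys <- offsets$offsets[lo:i]
      if (length(xs) < 2L) {
        shift[sel] <- ys[length(ys)]
      } else {
        fit <- theil_sen(xs, ys)
        shift[sel] <- fit$intercept + fit$slope * ts[sel]
      }
    }
  }
  out <- stream
  out$timestamps <- ts + shift
  out$clock_id <- offsets$receiver_clock_id
  attr(out, "n_extrapolated") <- n_extrapolated
  out
}

# Theil-Sen estimator: median of pairwise slopes, intercept the median of
# the residuals y - slope * x.
theil_sen <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2L, length(y) == n)
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  keep <- upper.tri(dx) & dx != 0
  slope <- stats::median(dy[keep] / dx[keep])
  intercept <- stats::median(y - slope * x)
  list(slope = slope, intercept = intercept)
}

#' Robust linear trend of a clock-offset series
#'
#' Fits an outlier-resistant (Theil-Sen) line through the trailing `window`
#' measurements of a clock-offset series: the slope is the median of all
#' pairwise slopes and the intercept the median residual.  Also returns the
#' fitted offset value at the window's end.
#'
#' @param offsets A [clock_offset_series()].
#' @param window Number of trailing measurements to use (default: all);
#'   at least 2 points are required.
#' @return A list with `slope` (s/s), `intercept` (seconds), `at` (time of
#'   the last measurement used) and `value` (fitted offset at `at`).
#' @export
fit_robust_offset_trend <- function(offsets, window = length(offsets$times)) {
  stopifnot(inherits(offsets, "clock_offset_series"))
  n <- length(offsets$times)
  if (n < 2L) stop("need at least 2 offset measurements", call. = FALSE)
  window <- min(as.integer(window), n)
  if (window < 2L) stop("`window` must be >= 2", call. = FALSE)
  sel <- (n - window + 1L):n
  fit <- theil_sen(offsets$times[sel], offsets$offsets[sel])
  at <- offsets$times[n]
  list(slope = fit$slope, intercept = fit$intercept, at = at,
       value = fit$intercept + fit$slope * at)
}
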