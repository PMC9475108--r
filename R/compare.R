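#' Compare clock-offset records from two recorders
#'
#' Two recording programs running side by side request clock-correction
#' offsets at slightly different times, so their records are paired by
#' nearest measurement time: measurements whose times differ by less than
#' `max_time_gap` form a pair, and the paired differences `a - b` are
#' summarized.  Differences beyond +/-10 ms are counted as outliers.
#'
#' @param a,b [clock_offset_series()] objects for the same clock pair.
#' @param max_time_gap Maximum time difference for pairing, seconds
#'   (default 2.5, half the standard 5 s measurement interval).
#' @param outlier_limit Limit beyond which a difference counts as an
#'   outlier, seconds (default 0.010).
#' @return An object of class `offset_comparison`: list with
#'   `paired_differences` (seconds), `mean_difference`,
#'   `mean_abs_difference`, `outlier_count` and `n_pairs`.
#' @export
align_offset_records <- function(a, b, max_time_gap = 2.5,
                                 outlier_limit = 0.010) {
  stopifnot(inherits(a, "clock_offset_series"),
            inherits(b, "clock_offset_series"))
  if (!identical(a$sender_clock_id, b$sender_clock_id) ||
      !identical(a$receiver_clock_id, b$receiver_clock_id)) {
    stop("the two series must record the same clock pair", call. = FALSE)
  }
  pairs <- pair_events(a$times, b$times, max_abs_offset = max_time_gap)
  if (nrow(pairs) == 0L) {
    stop("no offset measurements could be paired", call. = FALSE)
  }
  ia <- match(pairs$t_ref, a$times)
  ib <- match(pairs$t_obs, b$times)
  d <- a$offsets[ia] - b$offsets[ib]
  structure(
    list(paired_differences = d,
         mean_difference = mean(d),
         mean_abs_difference = mean(abs(d)),
         outlier_count = sum(abs(d) > outlier_limit),
         n_pairs = length(d)),
    class = "offset_comparison"
  )
}

#' @export
print.offset_comparison <- function(x, ...) {
  cat(sprintf(
    "<offset_comparison> %d pairs: mean %.4g ms, mean |diff| %.4g ms, %d outliers beyond +/-10 ms\n",
    x$n_pairs, 1e3 * x$mean_difference, 1e3 * x$mean_abs_difference,
    x$outlier_count))
  invisible(x)
}

#' Clipped histogram of paired offset differences
#'
#' Bins differences into symmetric bins on `[-clip_limit, clip_limit]`;
#' values beyond the limits are included in the outermost bins, so the
#' total count is conserved for any settings.
#'
#' @param differences Numeric vector, seconds.
#' @param bin_width Bin width, seconds (default 0.0005).
#' @param clip_limit Clip limit, seconds (default 0.010);
#'   `2 * clip_limit / bin_width` must be a whole number of bins.
#' @return A list with `edges` (length `nbins + 1`), `counts` (length
#'   `nbins`) and the settings.  Bins are left-closed, right-open, except
#'   the last bin which is closed.
#' @export
clipped_histogram <- function(differences, bin_width = 5e-4,
                              clip_limit = 0.010) {
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be positive", call. = FALSE)
  }
  if (!is.finite(clip_limit) || clip_limit <= 0) {
    stop("`clip_limit` must be positive", call. = FALSE)
  }
  nbins <- round(2 * clip_limit / bin_width)
  if (abs(nbins * bin_width - 2 * clip_limit) > 1e-9 * clip_limit) {
    stop("`clip_limit` must be a whole number of bins", call. = FALSE)
  }
  edges <- -clip_limit + bin_width * (0:nbins)
  x <- as.numeric(differences)
  # clip into the outer bins
  x <- pmin(pmax(x, edges[1L]), edges[nbins + 1L])
  idx <- floor((x - edges[1L]) / bin_width) + 1L
  idx[idx > nbins] <- nbins  # right edge / clipped-high values -> top bin
  idx[idx < 1L] <- 1L
  counts <- tabulate(idx, nbins)
  list(edges = edges, counts = counts, bin_width = bin_width,
       clip_limit = clip_limit, n = length(x))
}
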