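#' Latency-vs-recording-time plot
#'
#' Plots per-trial latency (ms) over recording time, one colour per
#' session -- the standard diagnostic for latency drift and between-session
#' lag variation.
#'
#' @param series A [latency_series()] or a list of them.
#' @return A ggplot object.
#' @export
plot_latency_series <- function(series) {
  if (inherits(series, "latency_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(time_min = s$trial_times / 60, latency_ms = 1e3 * s$latencies,
               session = s$session_id, stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = time_min, y = latency_ms,
                                   colour = session)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "recording time [min]", y = "latency [ms]",
                  colour = "session") +
    ggplot2::theme_minimal()
}

#' Histogram plot of clipped offset differences
#'
#' @param hist A histogram as returned by [clipped_histogram()].
#' @return A ggplot object.
#' @export
plot_offset_comparison <- function(hist) {
  mids <- (hist$edges[-1L] + hist$edges[-length(hist$edges)]) / 2
  df <- data.frame(mid_ms = 1e3 * mids,
                   share = hist$counts / max(1L, sum(hist$counts)))
  ggplot2::ggplot(df, ggplot2::aes(x = mid_ms, y = share)) +
    ggplot2::geom_col(width = 1e3 * hist$bin_width) +
    ggplot2::labs(x = "clock offset difference [ms]",
                  y = "relative occurrence") +
    ggplot2::theme_minimal()
}
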