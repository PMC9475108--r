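#' Example per-session timing summaries
#'
#' A small bundled table of published per-session timing-test results from
#' a portable hearing-device / ear-EEG measurement setup: lag and jitter (in
#' ms) of every timing-test session, for the three measurement scenarios
#' (I: marker vs. playback, II: EEG stream vs. analog input, III: full
#' in-the-loop chain) and two session durations (15 min and 3 h).  Useful
#' for demonstrating across-session-range summaries without running the
#' simulator.
#'
#' @return A data frame with columns `duration`, `session`, `scenario`,
#'   `lag_ms`, `jitter_ms`.
#' @seealso [across_session_range()], [condition_summary()]
#' @export
#' @examples
#' tab <- example_session_table()
#' s1 <- subset(tab, duration == "15min" & scenario == "I")
#' across_session_range(s1$lag_ms)  # 0.14 ms
example_session_table <- function() {
  path <- system.file("extdata", "session_summaries.csv",
                      package = "lsltiming", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
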