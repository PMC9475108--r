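test_that("lag and jitter have their closed forms and error contracts", {
  expect_equal(lag(c(5, 5, 5) * 1e-3), 5e-3)
  expect_equal(lag(c(-1, 1) * 1e-3), 0)
  expect_equal(jitter(c(1, 3) * 1e-3), sqrt(2) * 1e-3)
  expect_equal(jitter(rep(0.004, 10)), 0)
  expect_error(lag(numeric(0)), "empty")
  expect_error(jitter(0.5), "at least 2")
  s <- latency_series("I", 1:3, c(1, 2, 3) * 1e-3)
  expect_equal(lag(s), 2e-3)
})

test_that("lag, jitter and the range agree with brute-force accumulation", {
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(1000, mean = runif(1, -0.05, 0.05), sd = runif(1, 1e-4, 5e-3))
    expect_equal(lag(x), oracle_mean(x), tolerance = 1e-12)
    expect_equal(jitter(x), oracle_sd(x), tolerance = 1e-12)
    expect_equal(across_session_range(x), oracle_range(x), tolerance = 1e-12)
  }
})

test_that("the across-session range is max minus min and non-negative", {
  expect_equal(across_session_range(c(-1.56, -53.07, -10.5, -1.98, -21.67)),
               51.51)
  expect_equal(across_session_range(3.3), 0)
  expect_error(across_session_range(numeric(0)), "zero sessions")
})

test_that("timing metrics are shift and scale equivariant", {
  set.seed(13)
  x <- rnorm(500, 0.02, 0.003)
  lags <- c(lag(x), lag(x[1:100]), lag(x[101:500]))
  for (c0 in c(-0.05, 0.001, 0.2)) {
    expect_equal(lag(x + c0), lag(x) + c0)
    expect_equal(jitter(x + c0), jitter(x))
    expect_equal(across_session_range(lags + c0), across_session_range(lags))
  }
  for (k in c(0.1, 2, 7.5)) {
    expect_equal(lag(k * x), k * lag(x))
    expect_equal(jitter(k * x), k * jitter(x), tolerance = 1e-12)
    expect_equal(across_session_range(k * lags), k * across_session_range(lags),
                 tolerance = 1e-12)
  }
  # identical sessions have zero spread
  expect_equal(across_session_range(rep(lag(x), 4)), 0)
})

test_that("scenario I latencies recover the configured playout delay", {
  cfg <- session_config(schedule = stimulus_schedule(duration = 30),
                        sender = quiet_sender(playout_latency = 0.0327),
                        eeg_chain = quiet_chain(), protocol = quiet_protocol())
  b <- simulate_session(cfg, seed = 2)
  s <- latencies_scenario1(b$marker_stream, b$audio_stream)
  expect_length(s$latencies, 30)
  expect_true(all(abs(s$latencies - 0.0327) <= 1 / 16000))

  bz <- session_identity(120)
  sz <- latencies_scenario1(bz$marker_stream, bz$audio_stream)
  expect_true(all(abs(sz$latencies) <= 1 / 16000))
})

test_that("scenario II latencies are zero for an identity chain and signed", {
  b <- session_identity(120)
  eeg <- map_timeline(b$eeg_stream, b$offsets$eeg)
  s <- latencies_scenario2(eeg, b$audio_stream)
  expect_equal(s$scenario, "II")
  expect_true(all(abs(s$latencies) <= 1 / 16000))

  # a timestamp overcorrection produces negative latencies
  cfg <- session_config(schedule = stimulus_schedule(duration = 30),
                        sender = quiet_sender(),
                        eeg_chain = quiet_chain(timestamp_correction_bias = -0.020),
                        protocol = quiet_protocol())
  bn <- simulate_session(cfg, seed = 4)
  sn <- latencies_scenario2(map_timeline(bn$eeg_stream, bn$offsets$eeg),
                            bn$audio_stream)
  expect_true(all(sn$latencies < 0))
  expect_lt(abs(lag(sn) - (-0.020)), 1e-4)
})

test_that("the scenario III pipeline recovers an end-to-end latency", {
  cfg <- session_config(schedule = stimulus_schedule(duration = 60),
                        sender = quiet_sender(playout_latency = 0.025),
                        eeg_chain = quiet_chain(), protocol = quiet_protocol())
  b <- simulate_session(cfg, seed = 6)
  s <- latencies_scenario3(b$eeg_stream, b$marker_stream, b$offsets)
  expect_length(s$latencies, 60)
  expect_lt(abs(lag(s) - 0.025), 1 / 16000)
  expect_lt(jitter(s), 1 / 16000)
})

test_that("scenario III rejects epochs without threshold crossings", {
  b <- session_identity(120)
  dead <- b$eeg_stream
  dead$values[] <- 0
  expect_error(latencies_scenario3(dead, b$marker_stream, b$offsets),
               "no threshold crossings")
})

test_that("condition summaries stack sessions and report the spread", {
  mk <- function(id, lags) timing_summary(latency_series("I", seq_along(lags),
                                                         lags, session_id = id),
                                          duration_class = "15min")
  cond <- condition_summary(list(mk("a", rnorm(20, 0.0327, 1e-4)),
                                 mk("b", rnorm(20, 0.0329, 1e-4)),
                                 mk("c", rnorm(20, 0.0326, 1e-4))))
  expect_equal(nrow(cond$sessions), 3)
  expect_gte(cond$delta_r_lag, 0)
  expect_gte(cond$delta_r_jitter, 0)
  expect_equal(cond$delta_r_lag,
               max(cond$sessions$lag) - min(cond$sessions$lag))
})
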