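make_offsets <- function(times, offsets) {
  clock_offset_series("receiver", "remote", times, offsets)
}

make_stream <- function(ts) {
  sampled_stream("s", "remote", 100, ts, seq_along(ts))
}

test_that("constant offsets shift all timestamps by exactly that constant", {
  off <- make_offsets(seq(0, 50, by = 5), rep(0.123, 11))
  st <- make_stream(seq(0.5, 49.5, by = 0.5))
  for (m in list(timeline_map_method("most_recent_offset"),
                 timeline_map_method("robust_linear", window = 5))) {
    mapped <- map_timeline(st, off, m)
    expect_equal(mapped$timestamps, st$timestamps + 0.123)
    expect_identical(mapped$clock_id, "receiver")
  }
})

test_that("a single offset measurement produces a uniform shift", {
  off <- make_offsets(10, 0.05)
  st <- make_stream(c(1, 10, 20))
  mapped <- map_timeline(st, off)
  expect_equal(mapped$timestamps, st$timestamps + 0.05)
  expect_equal(attr(mapped, "n_extrapolated"), 1L)  # the timestamp before t=10
})

test_that("most-recent-offset mapping is piecewise constant between measurements", {
  off <- make_offsets(c(0, 5, 10), c(0.01, 0.02, 0.03))
  st <- make_stream(c(5.1, 6, 9.9))
  mapped <- map_timeline(st, off)
  expect_equal(mapped$timestamps - st$timestamps, rep(0.02, 3))
})

test_that("mapping error under linear drift is bounded by drift x interval", {
  d <- 5e-5
  interval <- 5
  recv <- clock_model(); send <- clock_model(drift_rate = d)
  off <- measure_clock_offsets(recv, send, offset_protocol_config(
    interval = interval, measurement_noise_sd = 0), duration = 100, seed = 1,
    sender_clock_id = "remote")
  events_true <- sort(runif(200, 0, 100))
  st <- make_stream(clock_time(send, events_true))
  mapped <- map_timeline(st, off)
  err <- abs(mapped$timestamps - events_true)
  # brute-force geometric bound: within one interval the offset changes by d*interval
  expect_true(all(err <= d * interval + 1e-12))
  # and the bound is tight somewhere near the end of an interval
  expect_gt(max(err), 0.5 * d * interval)
})

test_that("mapping validates its inputs", {
  st <- make_stream(1:3)
  expect_error(map_timeline(st, make_offsets(numeric(0), numeric(0))), "empty")
  wrong <- clock_offset_series("receiver", "other", c(1, 2), c(0, 0))
  expect_error(map_timeline(st, wrong), "does not match")
})

test_that("Theil-Sen fit is exact on clean lines and resists 150 ms outliers", {
  x <- seq(0, 295, by = 5)
  y <- 2e-3 + 4e-6 * x
  off <- make_offsets(x, y)
  fit <- fit_robust_offset_trend(off)
  expect_equal(fit$slope, 4e-6, tolerance = 1e-12)
  expect_equal(fit$intercept, 2e-3, tolerance = 1e-12)
  expect_equal(fit$value, 2e-3 + 4e-6 * max(x), tolerance = 1e-12)

  # two points: the line through them
  f2 <- fit_robust_offset_trend(make_offsets(c(0, 10), c(1, 3)))
  expect_equal(f2$slope, 0.2)
  expect_equal(f2$intercept, 1)

  # 10% of points displaced by +150 ms: slope unchanged to 1e-7 s/s
  y_out <- y
  y_out[seq(5, 60, by = 10)] <- y_out[seq(5, 60, by = 10)] + 0.150
  fo <- fit_robust_offset_trend(make_offsets(x, y_out))
  expect_lt(abs(fo$slope - fit$slope), 1e-7)

  expect_error(fit_robust_offset_trend(make_offsets(1, 1)), "at least 2")
})

test_that("robust-linear mapping converges to the true drift line", {
  d <- 2e-5
  x <- seq(0, 500, by = 5)
  set.seed(1)
  y <- 1e-3 + d * x
  y[sample(length(y), 10)] <- y[sample(length(y), 10)] + 0.15  # outliers
  off <- make_offsets(x, y)
  st <- make_stream(seq(100, 400, by = 7))
  mapped <- map_timeline(st, off, timeline_map_method("robust_linear", window = 20))
  expect_equal(mapped$timestamps, st$timestamps + 1e-3 + d * st$timestamps,
               tolerance = 1e-9)
})
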