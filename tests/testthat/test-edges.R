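test_that("rising edges of an ideal square wave sit at the onsets", {
  sched <- stimulus_schedule(duration = 10)
  onsets <- generate_stimulus_onsets(sched)
  s <- render_square_wave(onsets, sched, rate = 1000, t_start = -0.5)
  edges <- detect_rising_edges(s)
  expect_length(edges, length(onsets))
  expect_true(all(abs(edges - onsets) <= 1 / 1000))
})

test_that("flat signals yield no edges", {
  expect_identical(detect_rising_edges(sampled_stream("z", "c", 10, 1:50,
                                                      rep(0, 50))),
                   numeric(0))
  expect_identical(detect_rising_edges(sampled_stream("z", "c", 10, 1:50,
                                                      rep(3.2, 50))),
                   numeric(0))
  expect_error(detect_rising_edges(sampled_stream("z", "c", 10, numeric(0),
                                                  numeric(0))), "empty")
  expect_error(detect_rising_edges(sampled_stream("z", "c", 10, 1:3, 1:3),
                                   threshold_fraction = 1.5), "threshold")
})

test_that("edge count under additive noise matches a dense threshold-scan oracle", {
  sched <- stimulus_schedule(duration = 30)
  onsets <- generate_stimulus_onsets(sched)
  s <- render_square_wave(onsets, sched, rate = 500, t_start = -0.5)
  set.seed(21)
  s$values <- s$values + rnorm(length(s$values), 0, 0.05)
  edges <- detect_rising_edges(s, 0.5, min_separation = 0.03)
  n_oracle <- oracle_edge_count(s$timestamps, s$values, 0.5 * max(s$values),
                                0.03)
  expect_equal(length(edges), n_oracle)
  expect_equal(length(edges), length(onsets))
})

test_that("event pairing handles shifts, dropouts and ties like the brute force", {
  r <- seq(0, 19, by = 1)
  expect_equal(pair_events(r, r)$t_obs, r)
  p <- pair_events(r, r + 0.03)
  expect_equal(p$t_obs - p$t_ref, rep(0.03, 20))

  # one observed event missing: n-1 pairs, the dropout logged
  p2 <- pair_events(r, (r + 0.01)[-7])
  expect_equal(nrow(p2), 19)
  expect_equal(attr(p2, "dropped"), c(reference = 1L, observed = 0L))

  # empty inputs
  expect_equal(nrow(pair_events(numeric(0), r)), 0)

  # randomized cases against the full-matrix assignment oracle
  set.seed(33)
  for (i in 1:5) {
    ref <- sort(runif(15, 0, 15))
    obs <- sort(c(ref[-sample(15, 3)] + rnorm(12, 0, 0.05), runif(2, 0, 15)))
    got <- pair_events(ref, obs, max_abs_offset = 0.2)
    want <- oracle_pair(ref, obs, 0.2)
    expect_equal(got$t_ref, want$t_ref)
    expect_equal(got$t_obs, want$t_obs)
  }
})

test_that("upsampling preserves constants, ramps, and step-crossing times", {
  t <- seq(0, 1, by = 1 / 250)
  con <- upsample_to(sampled_stream("c", "c", 250, t, rep(2, length(t))), 1000)
  expect_true(all(con$values == 2))
  expect_equal(con$nominal_rate, 1000)

  ramp <- upsample_to(sampled_stream("r", "c", 250, t, 3 * t), 16000)
  expect_equal(ramp$values, 3 * ramp$timestamps, tolerance = 1e-12)

  # step signal: interpolant crossing within one source sample of the step,
  # and half-max crossing equal to a dense-evaluation oracle
  step_t <- 0.4012
  v <- as.numeric(t >= step_t)
  up <- upsample_to(sampled_stream("s", "c", 250, t, v), 16000)
  cross <- detect_rising_edges(up)
  expect_length(cross, 1)
  expect_lt(abs(cross - step_t), 1 / 250)
  dense_t <- seq(0, 1, length.out = 2000001)
  dense_v <- approx(t, v, xout = dense_t)$y
  oracle_cross <- dense_t[which(dense_v[-1] >= 0.5 & dense_v[-length(dense_v)] < 0.5)[1] + 1]
  expect_lt(abs(cross - oracle_cross), 1 / 16000)

  expect_error(upsample_to(sampled_stream("s", "c", 250, 1, 1), 1000),
               "at least 2")
  expect_error(upsample_to(sampled_stream("s", "c", 250, t, v), 100),
               "target_rate")
})
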