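test_that("simulated sessions conserve trial counts", {
  cfg <- session_config(schedule = stimulus_schedule(duration = 25),
                        sender = quiet_sender(0.0327),
                        eeg_chain = quiet_chain(), protocol = quiet_protocol())
  b <- simulate_session(cfg, seed = 1)
  n_onsets <- length(generate_stimulus_onsets(cfg$schedule))
  expect_equal(length(b$marker_stream$timestamps), n_onsets)
  expect_equal(length(b$ground_truth$onsets), n_onsets)
  expect_equal(length(b$ground_truth$playout_delay), n_onsets)
})

test_that("sessions are byte-identical under the same seed", {
  cfg <- session_config(schedule = stimulus_schedule(duration = 15),
                        eeg_chain = eeg_chain_config(additive_noise_sd = 0.01),
                        eeg_clock = clock_model(initial_offset = 0.2,
                                                drift_rate = 1e-5,
                                                timestamp_noise_sd = 1e-5))
  a <- simulate_session(cfg, seed = 10)
  b <- simulate_session(cfg, seed = 10)
  expect_identical(a, b)
  c <- simulate_session(cfg, seed = 11)
  expect_false(identical(a$eeg_stream$timestamps, c$eeg_stream$timestamps))
})

test_that("sender places audio edges playout_latency after the markers", {
  snd <- simulate_sender(sender_config(playout_latency = 0.0327,
                                       playout_jitter_sd = 0),
                         stimulus_schedule(duration = 10), seed = 1)
  edges <- detect_rising_edges(snd$audio)
  expect_length(edges, 10)
  expect_true(all(abs(edges - (snd$onsets + 0.0327)) <= 1 / 16000))
  expect_equal(snd$markers$timestamps, snd$onsets)  # identity sender clock
  expect_equal(snd$playout_delay, rep(0.0327, 10))
  expect_error(simulate_sender(sender_config(playout_latency = NaN),
                               stimulus_schedule(duration = 5)), "finite")
})

test_that("playout jitter propagates into the scenario I jitter estimate", {
  sd0 <- 8e-5
  snd <- simulate_sender(sender_config(playout_latency = 0.01,
                                       playout_jitter_sd = sd0),
                         stimulus_schedule(duration = 400), seed = 12)
  s <- latencies_scenario1(snd$markers, snd$audio)
  n <- length(s$latencies)
  # interpolated edge times carry uniform quantization of one audio sample,
  # so the expected jitter is sqrt(sd0^2 + (1/rate)^2 / 12)
  expected <- sqrt(sd0^2 + (1 / 16000)^2 / 12)
  expect_lt(abs(jitter(s) - expected), 3 * expected / sqrt(2 * (n - 1)))
})

test_that("a parameter-free EEG chain resamples the analog input exactly", {
  sched <- stimulus_schedule(duration = 8)
  analog <- render_square_wave(generate_stimulus_onsets(sched), sched, 16000)
  chain <- quiet_chain(antialias_halfwidth = 0)
  eeg <- simulate_eeg_acquisition(analog, chain, seed = 1)
  expect_equal(eeg$nominal_rate, 250)
  # values equal the analog signal at the nominal grid times
  ref <- approx(analog$timestamps, analog$values, xout = eeg$timestamps)$y
  expect_equal(eeg$values, ref)
  # chunked delivery never alters timestamps
  eeg2 <- simulate_eeg_acquisition(analog, quiet_chain(antialias_halfwidth = 0,
                                                       chunk_period = 0.2),
                                   seed = 1)
  expect_identical(eeg$timestamps, eeg2$timestamps)
  expect_identical(eeg$values, eeg2$values)
  expect_error(eeg_chain_config(eeg_rate = 0), "eeg_rate")
  expect_error(eeg_chain_config(chunk_period = 1e-4), "chunk_period")
})

test_that("timestamp overcorrection shifts EEG timestamps, not values", {
  sched <- stimulus_schedule(duration = 8)
  analog <- render_square_wave(generate_stimulus_onsets(sched), sched, 16000)
  a <- simulate_eeg_acquisition(analog, quiet_chain(), seed = 1)
  b <- simulate_eeg_acquisition(analog,
                                quiet_chain(timestamp_correction_bias = -0.02),
                                seed = 1)
  expect_equal(b$timestamps, a$timestamps - 0.02)
  expect_identical(b$values, a$values)
})

test_that("derived substream seeds are stable and label-dependent", {
  derive_seed <- lsltiming:::derive_seed
  expect_identical(derive_seed(1, "clock"), derive_seed(1, "clock"))
  expect_false(derive_seed(1, "clock") == derive_seed(1, "schedule"))
  expect_false(derive_seed(1, "clock") == derive_seed(2, "clock"))
  expect_true(derive_seed(.Machine$integer.max, "x") < 2^31)
})
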