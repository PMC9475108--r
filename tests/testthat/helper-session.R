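# Session fixtures are simulated once per test run and cached, so several
# test files can share the heavier 15-min (900-trial) recordings.

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, config, seed) {
  if (!exists(key, envir = .session_cache)) {
    assign(key, lsltiming::simulate_session(config, seed = seed),
           envir = .session_cache)
  }
  get(key, envir = .session_cache)
}

# quiet protocol/chain used by short structural tests
quiet_chain <- function(...) {
  lsltiming::eeg_chain_config(sampling_schedule_jitter_sd = 0,
                              additive_noise_sd = 0, ...)
}

quiet_protocol <- function(...) {
  lsltiming::offset_protocol_config(measurement_noise_sd = 0, ...)
}

quiet_sender <- function(playout_latency = 0, ...) {
  lsltiming::sender_config(playout_latency = playout_latency,
                           playout_jitter_sd = 0, ...)
}

# 15-min recovery sessions used by the acceptance suite
session_recovery_s1 <- function() {
  cached_session("s1", lsltiming::session_config(
    schedule = lsltiming::stimulus_schedule(duration = 900),
    sender = lsltiming::sender_config(playout_latency = 0.0327,
                                      playout_jitter_sd = 8e-5),
    eeg_chain = quiet_chain(),
    protocol = quiet_protocol()), seed = 42)
}

session_recovery_s2 <- function() {
  cached_session("s2", lsltiming::session_config(
    schedule = lsltiming::stimulus_schedule(duration = 900),
    sender = quiet_sender(),
    eeg_chain = lsltiming::eeg_chain_config(
      timestamp_correction_bias = -0.020,
      sampling_schedule_jitter_sd = 3e-3,
      additive_noise_sd = 1e-3),
    protocol = lsltiming::offset_protocol_config(measurement_noise_sd = 1e-4)),
    seed = 7)
}

session_recovery_s3 <- function() {
  cached_session("s3", lsltiming::session_config(
    schedule = lsltiming::stimulus_schedule(duration = 900),
    sender = quiet_sender(playout_latency = 0.025),
    eeg_chain = lsltiming::eeg_chain_config(
      sampling_schedule_jitter_sd = 3e-3,
      additive_noise_sd = 1e-3),
    protocol = lsltiming::offset_protocol_config(measurement_noise_sd = 1e-4)),
    seed = 11)
}

# identity chain: no latency, no jitter, exact offsets
session_identity <- function(duration = 120) {
  cached_session(paste0("identity", duration), lsltiming::session_config(
    schedule = lsltiming::stimulus_schedule(duration = duration),
    sender = quiet_sender(),
    eeg_chain = quiet_chain(),
    protocol = quiet_protocol()), seed = 3)
}
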