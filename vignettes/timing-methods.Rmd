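---
title: "Methods: simulating and measuring audio/EEG stream alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring audio/EEG stream alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `lsltiming`, the reasoning behind
its numerical choices, and what its synthetic sessions do and do not
emulate. It states no measurement result that the package's tests and
acceptance script do not themselves compute.

## 1. The timing model

A multi-device recording setup is modeled as three clocks: a *receiver*
clock defining the common timeline (identity by default), a *sender* clock
timestamping the event markers, and an *EEG* clock timestamping the EEG
stream. Each `clock_model()` maps true time to a local reading

$$\mathrm{local}(t) = t + o + d\,t + a\,(1 - e^{-t/\tau}) + \varepsilon,$$

with initial offset $o$ (s), linear drift $d$ (s/s, ppm scale — the
constructor rejects $|d| \ge 10^{-3}$, far above any crystal), a saturating
term of amplitude $a$ and timescale $\tau$ for rate differences that settle
as a device warms up, and optional per-read Gaussian noise $\varepsilon$.
With all parameters zero the mapping is exactly the identity, which anchors
the pipeline's identity-limit tests.

Clock-correction offsets are measured on a regular grid starting at $t=0$
(`floor(duration/interval) + 1` measurements; the protocol only fixes the
interval, the grid origin is this package's convention). Offsets are stored
as **receiver minus sender** local time, so mapping a remote stream into
the common timeline is purely additive — each timestamp gains either the
most recent offset measured at or before it (the default; deliberately
unsmoothed and therefore conservative) or the value of a robust line fitted
through a trailing window of measurements. Timestamps before the first
measurement reuse the first measurement; the count of such extrapolations
is reported in an `n_extrapolated` attribute rather than silently hidden,
since behavior before a smoothing window fills is implementation-defined
territory in real recorders.

Theil–Sen (median of pairwise slopes, intercept the median residual) is the
concrete choice of "outlier-resistant linear fit": it is deterministic, has
a 29% breakdown point — far above the sporadic-outlier rates seen in
offset records — and is exact on clean linear drift, which makes its
contract directly testable.

## 2. The synthetic session

`simulate_session()` composes the emulated signal flow: the sender plays
60 ms rectangular pulses at 1 Hz (half-open intervals
$[\mathrm{onset}, \mathrm{onset}+\mathrm{width})$; an onset at sample time
takes the pulse amplitude, the sample at onset + width is zero) and emits a
marker per pulse; the physical audio is fed into the EEG chain; offsets are
measured every 5 s. One integer seed drives everything through named
substreams (playout, schedule, value noise, protocol, clock reads), so
identical `(config, seed)` pairs give byte-identical bundles and each
component can be tested in isolation.

Key parameters (defaults in parentheses):

* **Stimulus** — pulse width 0.060 s, rate 1 Hz, duration 900 s; the two
  study conditions are 900 s (900 trials) and 10,800 s (10,800 trials).
* **Sender** — audio rate 16 kHz; playout latency 0.0327 s with per-trial
  jitter sd $8\times10^{-5}$ s. These defaults describe a block-based audio
  path whose lag is a block-size/sampling-rate constant with sub-0.1 ms
  trial-to-trial variation.
* **EEG chain** — 250 Hz; constant acquisition delay plus a constant
  `timestamp_correction_bias` that may be negative (a streaming app
  overcorrecting for wireless transmission latency makes edges appear
  *before* the physical input); a stochastic sampling schedule
  (below); internal drift of the ADC clock against the timestamp counter;
  additive value noise; chunked delivery, which affects availability
  order only — the timestamps are assigned at acquisition, which is the
  only way the negative measured lags can arise.
* **Offset protocol** — interval 5 s, measurement noise sd $10^{-4}$ s,
  sporadic outliers of 0.15 s magnitude with configurable probability.

### The stochastic sampling schedule

The schedule offset is an AR(1) (discretized Ornstein–Uhlenbeck) process
added to the sample timestamps, with marginal sd
`sampling_schedule_jitter_sd` (default 3 ms) and correlation timescale
`schedule_jitter_timescale` (default 0.2 s). Two considerations force the
autocorrelated form:

1. *Physics*: OS/driver/transmission scheduling errors are block-coherent —
   neighbouring samples of a wireless EEG stream share almost the same
   timing error, while errors a second apart are essentially independent.
2. *Identifiability*: with independent per-sample jitter, the two samples
   straddling an edge carry independent errors, so a configured 3 ms
   schedule jitter would appear as $\approx 3/\sqrt2$ ms of trial-latency
   jitter plus a quantization floor — the generator's headline parameter
   would not mean what it says. With a coherent offset, the straddling
   pair shifts together and the configured sd transfers one-to-one into
   per-trial latency jitter, which the recovery tests verify at $N=900$.

With the default timescale, offsets of samples 4 ms apart are correlated at
$\rho \approx 0.98$ (coherent across an edge) while trials 1 s apart are
uncorrelated, and consecutive timestamp increments stay monotone by a wide
margin (the simulator refuses configurations that would break
monotonicity rather than silently reordering samples).

### The anti-alias front end

The chain applies a boxcar (moving-average) filter of half-width one EEG
sample period (8 ms full width at 250 Hz) to the analog signal before
sampling. Besides being physically present in any real amplifier, the
boxcar has a property the analysis depends on: its step response is an
exactly linear ramp spanning two sample periods, so the two samples
straddling an edge always lie on that ramp and *linear interpolation
recovers the crossing time exactly*, independent of sampling phase. Without
it, a vertical edge sampled at 250 Hz yields a midpoint-of-gap crossing
estimate with up to 2 ms of phase-dependent bias, and an identity
(all-parameters-zero) chain would not reproduce zero latency. The only
residual artifact is half an analog sample (0.031 ms at 16 kHz) from the
half-open pulse convention, well below the one-upsampled-sample tolerance
the pipeline promises.

### Internal EEG drift

The latency drift of interest survives clock correction, so it cannot live
on the clock the offset protocol measures. The chain therefore models
drift of the sampling (ADC) clock relative to the counter used for
timestamping: `internal_drift_rate` plus a saturating term
(`internal_drift_amplitude`, `internal_drift_timescale`), the same
functional form as `clock_model()`. A linear term reproduces the
near-linear 15-min regime; the saturating term reproduces multi-hour
latency curves that flatten over time. Conversely, drift placed on the EEG
*device* clock is removed by timeline mapping and becomes visible only
when correction is withheld (`sync_method = "none"`), which is exactly how
the drift-recovery test operates.

## 3. The analysis pipeline

Edge detection returns linearly interpolated upward crossings of
`threshold_fraction * max(values)` (default one half), with a debounce that
merges crossings closer than `min_separation` (default 0.03 s, half the
pulse width); a constant signal has no edges and is an empty result, not an
error. Event pairing is one-to-one nearest-neighbour within
`max_abs_offset` (default 0.4 s, below half the stimulus period), accepted
greedily in order of increasing absolute offset with exact ties resolved
toward the earlier observed event — deterministic, and verified against a
brute-force assignment oracle. Unpaired events are dropped and counted.

Scenario III follows the ERP-style procedure: map both streams, upsample
the EEG to the audio rate (16 kHz) by linear interpolation — for a
vertical-edged test signal interpolation bounds the crossing-time error by
one source sample, and the half-maximum convention removes amplitude bias
— then epoch from −100 to +150 ms around each marker, subtract each
epoch's mean over −100 to −50 ms, average the epochs, and take the
threshold as half the maximum of the **baseline-corrected trial-averaged**
response (taking the half-maximum after baseline correction is a
documented choice, with the baseline level defined as zero). Each trial's
latency is the first upward threshold crossing relative to its marker.
Trials whose epoch window leaves the recording, or that never cross the
threshold, are excluded and counted in `dropped` (exclusion handling is
this package's decision; sessions simulated with the default 0.5 s
lead-in/lead-out padding lose no trials). An all-zero response is a hard
error ("no threshold crossings"), never an empty success.

Lag is the arithmetic mean, jitter the $N-1$ sample standard deviation, and
the across-session range $\Delta R = \max - \min$; all three are computed
at full precision and tested against brute-force accumulation at
$10^{-12}$ relative tolerance. The bundled example table stores lag/jitter
values rounded to two decimals as published, so ranges computed from it are
consistent with rounded inputs.

Drift fitting uses ordinary least squares for the linear model (minimum 10
trials) and Levenberg–Marquardt for the linear-plus-saturating model
(minimum 50 trials; timescale bounded away from zero; starting values from
a split-half slope heuristic). A non-converging nonlinear fit returns an
explicit failure with `NA` parameters — never a silent fall-back to the
linear model.

The recorder-comparison module pairs two offset records by nearest
measurement time within half the protocol interval (the two recorders
request corrections at different moments) and summarizes the differences;
its clipped histogram uses 0.5 ms bins on ±10 ms by default (the bin width
is a package choice; the clip rule — out-of-range values accumulate in the
outermost bins — conserves the total count for any settings).

## 4. What the simulator does and does not emulate

The generator reproduces the *timing structure* of a two-device setup:
marker-to-playback lag and jitter, counter-based timestamping with
coherent schedule noise, timestamp overcorrection, internal and
inter-device clock drift, periodic noisy offset measurements with
outliers. It makes no attempt at acoustic realism, real audio I/O,
real-time scheduling, Bluetooth protocol emulation, or physiological
signals (no ERPs, artifacts, or multi-channel data — the test signal is a
single-channel rectangle by design). The amplifier-to-phone
synchronization of real wireless EEG systems is proprietary and
unobservable; `timestamp_correction_bias` is a parametric stand-in for its
net effect, not a claim about any device's mechanism. Passing recovery
tests therefore demonstrates that the *pipeline* measures what the
*model* generates — evidence about real hardware still requires real
recordings, which the XDF importer admits unchanged (no de-jittering, no
offset smoothing on load).

## 5. Problem sizes and tolerances used in the test suite

Parameter-recovery tests run full 900-trial (15-min) sessions and compare
lag within $3\sigma/\sqrt N$ and jitter within $3\sigma/\sqrt{2(N-1)}$ of
the configured values — the 3-standard-error bands of the estimators
themselves. The identity limit is checked through the complete Scenario III
pipeline at one upsampled sample period ($1/16000$ s). The 3-h condition is
exercised at the marker/onset level (10,800 trials) and through the
saturating drift fit on directly generated 10,800-trial latency series
(amplitude 20 ms, timescale 2000 s); drift-slope recovery through the
waveform pipeline uses a 300 s session, where a 5 ppm drift accumulates
1.5 ms against ≤0.1 ms of configured noise. Round-trip and structural
tests use 5–30 s sessions. These sizes are the package's choices for
keeping the default suite fast while preserving each property's
discriminating power.

## 6. Known limitations

* Single-channel streams; multi-channel XDF files are imported by their
  first channel.
* The most-recent-offset mapping is piecewise constant, so mapped latency
  series inherit a sawtooth bounded by drift × interval; the robust-linear
  method removes it at the cost of a window convention.
* `detect_rising_edges()` thresholds on the observed maximum; heavy value
  noise inflates the maximum and shifts the effective threshold (the
  Scenario III path is immune, since it thresholds on the trial-averaged
  response).
* Greedy nearest pairing is not globally optimal assignment; for
  event trains separated by much more than the pairing window (the
  intended regime) the two coincide, and the tests compare against the
  brute-force oracle in exactly that regime.
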