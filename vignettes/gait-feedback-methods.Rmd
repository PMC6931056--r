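---
title: "Heel-strike detection and feedback emulation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heel-strike detection and feedback emulation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfeedback)
```

## The problem

Older adults who shuffle — contacting the ground foot-flat instead of
heel-first — walk slowly, stoop, and rarely reach the cadence (about 100
steps/min) that physical-activity guidelines treat as moderate intensity.
Wearable trainers address this with *knowledge of performance*: an
ankle-worn inertial sensor scores every step as it happens and sounds a
beep for each *good* (heel-first) step, rewarding the movement pattern
rather than reporting totals after the fact.

The measurable signature of a heel-first step lives in the sagittal-plane
angular velocity (AV) of the foot segment: after the mid-swing forward
rotation (a positive AV lobe of one to several hundred deg/s), heel contact
decelerates the foot sharply, producing a brief negative AV excursion. The
deeper that excursion, the stronger the heel strike; foot-flat contact
produces only a shallow dip. This package implements the complete
computational chain around that signature: signal I/O, a synthetic-gait
simulator with ground truth, batch and real-time (streaming) heel-strike
detection, per-step classification, walking-bout segmentation, session
metrics, and pre/post change reports, plus a small CLI.

## Signal model and conventions

A recording is a uniformly sampled 6-axis IMU trace (3-axis gyroscope in
deg/s, 3-axis accelerometer in m/s^2), default 100 Hz (configurable
25-500 Hz; the detector requires at least twice the smoothing corner).
Timestamps are implicit, session-relative seconds. One gyroscope axis —
`y` by mounting convention, configurable — carries sagittal rotation, with
the sign fixed so the post-heel-strike deceleration is *negative*; a
`sign = -1` flag accommodates mirror-mounted sensors. The CSV dialect is
deliberately rigid (fixed header, comma separator, `.` decimal, strictly
increasing timestamps uniform to 1%) so that format errors fail loudly
instead of corrupting analyses.

## Step detection

Detection runs in four stages on the sagittal trace:

1. **Smoothing.** Batch analysis uses a zero-phase 2nd-order Butterworth
   low-pass at 15 Hz (applied forward and backward), which removes sensor
   noise without shifting peaks; gait energy lies well below this corner.
   The streaming path uses the causal equivalent a device can actually run
   — a single-pole RC low-pass at the same corner — and accepts its small
   group delay.
2. **Swing gating.** Contiguous regions where the smoothed trace exceeds
   `swing_min_amp` (default +50 deg/s) are taken as mid-swing lobes; the
   region maximum (earliest sample on ties) is the swing peak. Gating on
   the large positive lobe first makes the detector robust to noise during
   stance and rest: rests produce no regions, hence no events.
3. **Deceleration search.** After each swing peak the deceleration minimum
   is sought within `search_window` (default 0.40 s) by a *sequential*
   scan that mirrors what a real-time device does: track the running
   minimum, and freeze it at the first sample that rebounds `rebound`
   (default 10 deg/s) above it, at window expiry, when the next swing lobe
   completes (the search hands over), or at end of data. A candidate
   yields an event only if its minimum is strictly negative — a "minimum"
   at or above zero is not a deceleration, and this rule discards junk
   candidates from truncated lobes at trace edges. The minimum's time is
   the heel-strike time (earliest sample on ties).
4. **Refractory and classification.** Events closer than `refractory`
   (default 0.40 s, comfortably below the ~0.5-0.9 s step periods seen
   clinically) to an accepted predecessor are dropped, earlier event wins.
   A step is *good* when its peak is at or below `threshold_av`; the
   boundary counts as good.

`threshold_av` defaults to -90 deg/s. The value separates the weak
foot-flat contacts observed in very impaired walkers (session means near
-48 deg/s with essentially no good steps) from heel-first stepping under
feedback (means of -100 deg/s and beyond); healthy reference values run
-300 to -500 deg/s. Devices expose low/medium/high variants of this
threshold, so it is fully configurable here.

### Peak measurement

The low-pass filter attenuates the narrow (~80 ms) deceleration lobe by
2-3%, which matters when peaks are compared against a threshold or
averaged into session statistics. The reported peak is therefore *not* the
filtered minimum: the detector fits a least-squares quadratic through the
five **raw** samples centred on the detected minimum and reports the
parabola's vertex value (standard sub-sample peak interpolation). The
vertex is accepted only if the fit is convex with its vertex within 2.5
samples of the centre; otherwise the fit's value at the centre (still a
5-point smoothed estimate, far more robust than one raw sample) is used,
then the raw centre sample, then the filtered minimum — the first
negative value in that chain wins. On noise-free strides this measures
peaks to better than 0.4%; under 10 deg/s sensor noise the per-step
measurement error is unbiased with SD around 7 deg/s.

## Real-time feedback emulation

The streaming module consumes samples one at a time (`push_sample`, or
`push_samples` for replay without per-sample call overhead) and emits a
feedback event — the logged stand-in for the audible beep — as soon as a
good step is confirmed. "Real time" here is the computational contract,
not audio: determinism and bounded latency are what can be tested.

The stream runs the *same rule set* as the batch detector on the causal
filter, as a strictly incremental state machine (filter memory, current
swing region and peak, one pending minimum search, a short raw-sample ring
buffer for peak refinement, refractory clock). Confirmation happens at the
rebound, window-expiry or hand-over sample; emission additionally waits
until the two raw samples after the minimum exist, so the refinement
window is complete. The emission latency is bounded by
`search_window + 0.05 s` (0.45 s at defaults; in practice the rebound rule
confirms within a few samples). The module's core contract, enforced by
tests on random sessions including chunk-split replays, is exact
agreement — times, refined peaks, and labels — between
`stream_steps()` and `detect_heel_strikes(smoothing = "causal")`.
A stream truncated mid-stride flushes its pending step at
`finalize_stream()`; a finalized stream accepts nothing further.

## Session metrics and change reports

`compute_metrics()` reports the proportion of good steps, cadence, total
walking time, and the mean, sample (n-1) SD, and coefficient of variation
(CV = 100 x SD / |mean|) of per-step peak AV. Design choices the
definitions leave open:

- AV statistics cover **all** steps, good and bad, matching how session
  means are reported clinically.
- Cadence divides steps by time inside walking bouts, not elapsed time, so
  rests do not deflate it.
- An empty session is flagged (`empty_session`) with the proportion set
  to 0 rather than raising, so batch pipelines keep running.

Bouts are maximal runs of steps whose successive gaps stay below
`gap_limit` (default 10 s — brief hesitations do not split a bout; the
clinically interesting unit is the >= 10 min bout counted by activity
guidelines). Each bout is padded by half the median within-bout stride
time on each side (0.5 s fallback for a lone step) so its duration
approximates walking time. `meets_guideline()` checks the
moderate-intensity pattern: cadence >= 100 steps/min and at least one
bout of >= 10 minutes.

`compare_sessions()` applies the clinical-importance rule: a parameter
changed by at least 10% *in its improving direction* (good steps up,
cadence up, peak AV more negative, CV down) relative to the magnitude of
the pre value is flagged important. When the pre proportion of good steps
is exactly 0 a ratio is meaningless; the report falls back to percentage
points and says so (`basis = "percentage_points"`). Swapping pre and post
flips the sign of every change (magnitudes differ, as with any
ratio-to-baseline measure). Cross-participant aggregation is deliberately
out of scope: these are single-subject reports.

## The synthetic-gait generator

Real recordings of this kind are not publicly deposited, so every stage is
validated against a simulator with known ground truth. A `gait_profile()`
fixes cadence, the heel-strike peak distribution (`av_mean`, `av_sd`), the
fraction of good-morphology steps `p_good`, the foot-flat attenuation
(default 0.4 — foot-flat contact still decelerates the foot, just weakly),
the swing amplitude, white sensor noise, a walk/rest bout plan, and a seed.

Each step contributes one stride waveform: quiet stance, a raised-cosine
swing lobe, and a Gaussian deceleration lobe (80 ms FWHM) centred at 80%
of the stride whose minimum is placed exactly on a sample. Only the
minimum's value and timing are contractual; the rest of the shape is a
plausible stand-in. Stride times jitter by 3% (Gaussian), so cadence is
recovered as an average. Peaks are drawn Normal and attenuated for bad
steps; a draw that comes out non-negative is clamped to -1 deg/s (a foot
always decelerates a little). The stored ground-truth `is_good` flag is
recomputed from the realized peak against the profile's threshold, so the
classification rule holds exactly even when the Normal tails cross the
threshold; with well-separated morphologies (the test profiles) the flags
coincide with the morphology labels. The generator owns a private RNG
stream (seeded once, draws consumed in a fixed documented order, caller
state restored), so sessions are bitwise-reproducible.

`profile_from_reference()` anchors profiles to published single-subject
observations spanning the clinically observed range (session AV means -48
to -263 deg/s, CV 10-59%, cadence 69-122, good-step proportions 0-100%),
with `av_sd` derived from the printed CV.

What the simulator does **not** emulate: real stance-phase detail, turning,
left/right asymmetry, soft-tissue artefact, drift, or a meaningful
accelerometer (those channels are plausible filler with no ground-truth
contract). Passing tests therefore demonstrate correctness of the
*computational chain* under controlled morphology — not clinical validity
on real recordings, which would need the original device constants and
signals.

## Numerical choices and degenerate inputs

- Problem sizes in the shipped tests: sessions of 20-300 s at 100 Hz,
  around 500 steps where parameter recovery is measured, 100-session
  batches for detection-fidelity and streaming-equivalence sweeps, and a
  1000-case brute-force oracle for bout segmentation.
- Ties: earliest sample wins for swing peaks and deceleration minima;
  refractory conflicts keep the earlier event.
- Empty traces, all-zero traces, header-only CSVs, single-sample series,
  and empty step lists all return well-defined empty results; errors are
  classed conditions (`gait_config_error`, `gait_validation_error`, ...)
  mapped to CLI exit codes 1 (usage/config) and 2 (data).
- CSV round trips are exact to < 1e-9 deg/s (15 significant digits).
- The filter is rejected (configuration error) when the sample rate is
  below twice the smoothing corner.

## Known limitations

- **Noise floor at the weakest-gait corner.** For a profile at session
  mean -48 deg/s with CV 59% — the weakest, most variable gait observed
  clinically — about 4.5% of generated peaks clamp near zero. A ~-1 deg/s
  deceleration is below the sensor-noise floor: the detector reports the
  search window's noise minimum (about -5 deg/s at 5 deg/s noise) or
  occasionally loses such a step to the refractory rule. The test suite
  computes the consequence: recovered CV underestimates the session's
  ground-truth CV by about 2.4 points there, just outside the +/-2-point
  recovery band that holds everywhere else in the clinical range. Peaks
  this small are physically indistinguishable from not stepping, so we
  report the behaviour rather than masking it.
- Classification exactly at the threshold is measurement-limited: peaks
  are measured to ~1% (noise-free), so true peaks within a fraction of a
  deg/s of the threshold can classify either way.
- The device's true threshold, confirmation rule and latency are published
  elsewhere; the defaults here are calibrated only to be *consistent* with
  the published session summaries, and the rebound confirmation rule is an
  engineering choice.
- Step detection assumes one instrumented ankle; cadence counts that
  foot's strides as "steps per minute" in the same convention as the
  published summaries.
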