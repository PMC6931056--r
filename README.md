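# gaitfeedback

Heel-strike detection, real-time feedback emulation, and session-level
gait-quality metrics for ankle-worn gyroscope recordings.

## What problem this solves

Shuffling gait — foot-flat ground contact instead of a heel-first strike —
is common in older adults and undermines both walking quality and the
cadence needed for health-promoting activity. Wearable gait trainers
counter it with per-step *knowledge of performance*: an ankle sensor
scores every step in real time and beeps for each **good** (heel-first)
step. The measurable signature is in the sagittal-plane angular velocity
(AV) of the foot: mid-swing produces a large positive lobe, and heel
contact decelerates the foot into a sharp negative excursion. A step is
good when that post-heel-strike deceleration peak crosses a threshold:

    good step  ⇔  peak AV ≤ threshold          (default threshold −90 °/s)

Session quality is summarised by the proportion of good steps, cadence
(steps/min), total walking time, the mean/SD of per-step peak AV, and its
coefficient of variation CV = 100·SD/|mean| (lower = more consistent
stepping), with walking bouts segmented by inter-step gaps and a
pre/post report flagging changes of ≥ 10 % in the improving direction as
clinically important.

This package is for researchers and engineers who need a tested,
reproducible implementation of that computational chain — including a
synthetic-gait simulator with exact ground truth, since clinical
recordings of this kind are not publicly deposited.

## What's in the box

- **signal I/O** — strict CSV dialect for 6-axis IMU traces
  (`read_imu_csv`, `write_imu_csv`, `extract_sagittal`), round-trip exact
  to < 1e-9 °/s.
- **synthetic gait** — `gait_profile()` / `simulate_session()` generate
  walking sessions (stance + raised-cosine swing lobe + 80 ms Gaussian
  deceleration lobe per stride; walk/rest bouts; sensor noise) with
  per-step ground truth; `profile_from_reference()` anchors profiles to
  published single-subject observations spanning AV means −48…−263 °/s,
  CV 10–59 %, cadence 69–122.
- **step detection** — `detect_heel_strikes()` (zero-phase Butterworth
  smoothing, swing gating, windowed minimum search, parabolic peak
  refinement on raw samples, refractory rule), `classify_step()`,
  `segment_bouts()`.
- **feedback stream** — `feedback_stream()` / `push_samples()` /
  `finalize_stream()`: a causal, strictly incremental re-implementation of
  the same rules that emits a beep event per good step with latency
  ≤ 0.45 s, provably identical to batch detection on the causal filter.
- **session metrics** — `compute_metrics()`,
  `coefficient_of_variation()`, `compare_sessions()` (the ≥ 10 % rule),
  `meets_guideline()` (cadence ≥ 100 and a ≥ 10-min bout).
- **CLI** — `inst/cli/gaitfb` with `simulate`, `analyze`, `stream`,
  `compare` subcommands over YAML run configs (exit codes: 0 ok,
  1 usage/config, 2 data).

## Worked example

Simulate a pre/post pair anchored to one published participant (B: 43 %
good steps before training, 80 % after), analyse both sessions, and
compare:

```r
library(gaitfeedback)

pre  <- simulate_session(profile_from_reference("B", "pre",  "without",
          bout_plan = list(c(120, 0)), seed = 1L))
post <- simulate_session(profile_from_reference("B", "post", "without",
          bout_plan = list(c(120, 0)), seed = 2L))

analyze <- function(sim) {
  ev <- detect_heel_strikes(extract_sagittal(sim$series))
  compute_metrics(ev, segment_bouts(ev))
}
m_pre <- analyze(pre); m_post <- analyze(post)
print(m_pre)
print(m_post)
print(compare_sessions(m_pre, m_post))
```

```
<gait_metrics> 189 steps (24.3% good), cadence 94.9 steps/min,
  walking time 119.5 s in 1 bout(s) (0 of >= 10 min),
  peak AV mean -61.7 deg/s, SD 38.3, CV 62.0%
<gait_metrics> 208 steps (61.5% good), cadence 104.0 steps/min,
  walking time 120.0 s in 1 bout(s) (0 of >= 10 min),
  peak AV mean -109.2 deg/s, SD 49.2, CV 45.0%
  pct_good     24.3 ->     61.5   +152.8%   ** important
  cadence      94.9 ->    104.0     +9.6%
  av_mean     -61.7 ->   -109.2    +76.8%   ** important
  av_cv        62.0 ->     45.0    +27.4%   ** important
=> clinically important change
```

Reading the output: the detector found 189 strides in the 2-minute pre
session, of which 24.3 % had a deceleration peak at or below −90 °/s; the
post session is faster (104 steps/min), strikes far harder on average
(−109.2 °/s), and is more consistent (CV down 17 points). Three of the
four parameters improved by more than 10 % in their improving direction,
so the change report flags the session pair as a clinically important
improvement. The estimates track the simulation's ground truth closely
(truth: 24.3 %/62.0 % good, means −61.4/−109.1 °/s, CV 63.1/45.1) — note
that realized session summaries legitimately differ from the printed
anchor cells whenever the peak distribution straddles the threshold, which
is exactly what happens in weak, variable gait.

The same pipeline from the shell:

```sh
gaitfb simulate --out pre.csv  --reference B:pre:without  --duration 120 --seed 1
gaitfb analyze  --in pre.csv   --report pre.json
gaitfb stream   --in pre.csv   --events beeps.json
gaitfb compare  --pre pre.json --post post.json --out change.json
```

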