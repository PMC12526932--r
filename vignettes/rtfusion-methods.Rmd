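---
title: "Methods: simulating and analysing smartphone audio-tactile RT experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing smartphone audio-tactile RT experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtfusion)
```

## The measurement problem

Reaction-time (RT) paradigms on smartphones face two timing obstacles.
First, stimulus delivery: the audio and vibration subsystems add
device-specific latencies, so the interval between an auditory and a tactile
stimulus as *commanded* differs from the interval as *delivered*.  A stable
offset (accuracy error) can be corrected in software; trial-to-trial jitter
(precision error) cannot, and is what limits a device's usability.  Second,
response logging: touchscreens scan at roughly 120 Hz, so a tap's logged
timestamp is quantized to an ~8.33 ms frame grid and further delayed by the
OS input pipeline.  Multisensory effects of interest are on the order of
20-50 ms, so ~8 ms of response quantization is a substantial fraction of the
signal.

The accelerometer offers a way out: it samples much faster (~500 Hz on
capable hardware, i.e. 2 ms resolution) and senses the physical impulse of
the finger strike directly, bypassing the input pipeline.  This package
implements that idea end to end, entirely in simulation, so every stage of
the measurement and analysis chain can be tested without hardware or
participants.

## The onset detector and fusion rule

The detector works on the magnitude of the 3-axis acceleration,

$$\mathrm{mag}_n = \sqrt{a_{x,n}^2 + a_{y,n}^2 + a_{z,n}^2},$$

which makes it insensitive to device orientation.  The change signal is an
exponentially weighted moving average (EWMA) of the absolute successive
difference:

$$y_n = |x_{n-1} - x_n|\,(1 - \alpha) + \alpha\, y_{n-1}, \qquad y_1 = 0,$$

with `x` the magnitude series.  A constant input gives $y \equiv 0$; a tap
produces a sharp elevation.  We initialise $y_1 = 0$ because the envelope of
an unseen past difference is zero.  One ordering question is genuinely open:
smoothing could be applied per axis before the norm, or to the norm itself.
We compute the magnitude first and smooth it, because a single scalar
envelope admits a single threshold, which is how the thresholding step is
described in practice.

A tap onset is reported at the first sample where $y$ rises to or above a
threshold (the onset, not the apex, is the proxy for physical contact), and
further reports are suppressed for a refractory period.  Parameters, with
defaults and rationale:

* `alpha = 0.5` -- one-sample memory halving; heavier smoothing blunts
  onsets, lighter smoothing admits noise.  Exposed because the right value
  is device-dependent and has to be calibrated.
* `threshold` -- in acceleration units; no universal default is possible
  because it depends on the noise floor.  `calibrate_threshold()` estimates
  the baseline envelope SD on a tap-free segment and multiplies by a safety
  factor `k` (default 8).
* `refractory_ms = 50` -- far below any plausible inter-response interval,
  far above the few-sample width of one tap transient.
* `window_ms` -- the fusion search window, defaulting to one touchscreen
  frame period of the device (8.33 ms at 120 Hz).

The fusion rule: once a touchscreen event is logged at time $L$, search
$[L - w, L]$ for accelerometer onsets; if any exist, the *most recent*
(latest) one replaces $L$ as the response time, otherwise $L$ stands.  Two
consequences are worth noting because the tests pin them: the fused response
time never exceeds the touchscreen time, and on a noiseless 500 Hz / 120 Hz
simulation the fused error is bounded by one accelerometer sample (2 ms)
while the touchscreen-only error reaches one frame (~8.33 ms).

A detail about the peak-count monotonicity property: raising the threshold
cannot increase the number of detected onsets *once the threshold is above
the envelope noise floor*.  Below the floor the envelope can stay
supra-threshold for long stretches, merging crossings, so the count is not
meaningful there; the property tests sweep thresholds from just above the
floor.

## The simulators

All simulators are pure functions of their arguments and a seed, so every
result in the package is exactly reproducible.

**Accelerometer traces.**  Constant gravity (9.81 on the z axis; orientation
effects are out of scope) plus independent Gaussian noise per axis.  Each
tap injects a 3-sample triangular pulse (half, full, half amplitude) on the
z axis starting at the first sample at-or-after the contact time.  The
waveform of a real tap is not documented anywhere we could rely on; the
triangle is the minimal shape producing one sharp successive-difference
peak, and nothing downstream depends on its exact form.

**Touch events.**  Contact time plus a Gaussian pipeline-latency draw
(truncated at zero), rounded *up* to the next frame boundary -- a scan-based
digitizer reports at the scan after contact, never before.

**The validation bench.**  Emulates the robotic-finger bench used to
qualify devices.  Per trial the device "commands" audio at $t_0$ and
vibration at $t_1 = t_0 + \Delta_1$ with $\Delta_1$ uniform in the
configured inter-stimulus range; the physically true onsets $t_0', t_1'$
add per-trial latency draws from the device profile.  A virtual robotic
finger taps a uniform draw (default 1-2 s) after $t_1'$; the tap is sensed
through the simulated accelerometer and touchscreen, and the internal
response stamp $t_2$ is the fused-detector output, while $t_2'$ is the true
tap time.  `bench_deltas()` then compares paired intervals:
sync delta $(t_1 - t_0) - (t_1' - t_0')$ and rt delta
$(t_2 - t_1) - (t_2' - t_1')$.  Constant injected latencies reappear as
delta means; latency SDs reappear in delta SDs (in quadrature where two
draws contribute).

The default inter-stimulus range is 500-1500 ms.  Descriptions of such
benches are not always self-consistent about the upper bound, so the range
is an explicit argument rather than a constant.

One physical subtlety: even with all latency noise at zero, the rt deltas
are not exactly constant, because the tap lands at an arbitrary phase of the
free-running 2 ms accelerometer grid; the detector's onset stamp carries a
sub-sample offset in $[0, 2)$ ms.  Exact SD = 0 therefore holds for the sync
deltas under zero latency SD, and for the rt deltas only when the trial
schedule is fully degenerate (fixed ISI and tap delay).  The tests pin both
facts, and the quantization bound is tested separately.  The bench does not
model the vibration's own accelerometer signature, only the tap transient.

**Device suitability.**  A device passes when the SDs of both delta lists
stay at or below a precision threshold, 10 ms by default -- an order of
magnitude below the typical human threshold for detecting multisensory
asynchrony (~50-100 ms).  The boundary is inclusive; that choice is
arbitrary but documented and pinned by tests.  The bundled profiles for five
consumer Android models carry their declared sensor rates and audio feature
flags; their latency means/SDs are synthetic stand-ins consistent with the
declared round-trip audio latencies, clearly labelled as such, because bench
measurements cannot be shipped.

## The paradigm and the synthetic cohort

The peripersonal-space task presents a 3250 ms sound, either *fixed* at
640 cm or *looming* from 640 cm to 20 cm, with a vibrotactile stimulus at
one of six onset delays (105, 1625, 2385, 2765, 2955, 3050 ms).  For a
looming sound the delay maps to the source distance at tactile onset
(640, 320, 160, 80, 40, 20 cm -- a logarithmic scale); the printed lookup
table is authoritative, not the nominal constant approach speed, which does
not exactly reproduce it.  Each block holds 48 experimental trials (4 per
movement x delay cell) and 24 catch trials (sound, no touch; response must
be withheld), and the default six blocks give 432 trials with 24
repetitions per cell and 33.3% catch.  The per-block split of cell
repetitions and the even assignment of catch trials to the two sound
conditions are design choices of this package (balanced blocks; no
confounding of movement with tactile expectancy) -- only the per-session
totals are externally fixed.

The cohort simulator draws each RT from a lognormal whose median is
`base_median[delay] + participant_offset - looming_effect[delay]` (the
effect applied only for looming sounds) and whose log-scale SD is
`sigma_log`.  Defaults and what they emulate:

* base medians 420, 400, 375, 355, 340, 330 ms across T1-T6: the
  expectancy-driven decline of RT along the trial.  Absolute baselines are
  not externally constrained; only the monotone decrease matters, and no
  test asserts their values beyond that shape.
* looming effect 0, 0, 22.5, 22.5, 22.5, 22.5 ms: facilitation confined to
  the four longest delays (source near the body), at the centre of the
  20-25 ms band this class of paradigms reports.  Applying it on the
  millisecond scale (shifting the median) rather than the log scale means
  the injected number is exactly the quantity the pipeline should recover.
* `sigma_log = 0.15`: right-skewed within-cell distributions typical of RT
  data, with cell SD ~15% of the median.
* `participant_sd_ms = 30`: between-participant spread of overall speed.
* `miss_prob = 0.014`: the ~1.4% miss rate typical of this easy detection
  task.  False alarms on catch trials are off by default.

What the generator does *not* emulate: sequential effects (fatigue,
learning, post-error slowing), anticipatory responses, within-session drift
of device latencies, and any sensorimotor model of the tapping finger.
Passing recovery tests therefore show that the pipeline is an unbiased
inverse of this generative model -- not that real data meet the model's
assumptions.

## The analysis pipeline

`analyze_sessions()` runs the stages in the order an analyst would:

1. **Exclusion.**  Participants whose miss rate exceeds the sample mean +
   3 SD (computed once, on the full sample, no re-screening) are dropped.
   The published convention in this literature reports the outcome, not the
   rule; mean + 3 SD reproduces the canonical case (a 9.0% misser against a
   1.4 +/- 2.0% sample, cutoff 7.4%) and is pluggable.  Note a small-sample
   fact the tests document: the largest attainable z inside a sample of
   size n is (n-1)/sqrt(n), so this rule cannot exclude anyone for n <= 10.
2. **RT filtering.**  Keep 100 <= RT <= 1000 ms, boundaries inclusive;
   "shorter than 100 and 1000" is read as outside that window, the only
   sensible interpretation, and the boundary convention is pinned by test.
   The removed fraction is reported against RT-bearing trials only.
3. **Condition means.**  RTs are ln-transformed, averaged per participant
   per (movement x delay) cell, and back-transformed -- the cell geometric
   mean, robust to the distribution's right skew.  Group cell means are
   arithmetic means of the participant values (not grand geometric means);
   SEM is across participants.  Facilitation at each delay is fixed minus
   looming, positive when looming is faster.
4. **ANOVA.**  Classical two-way within-subject decomposition (each effect
   against its effect-by-subject interaction), computed via `stats::aov()`
   with an `Error()` stratum and verified in the tests against a
   brute-force sums-of-squares oracle.  With n participants: df (1, n-1)
   for movement, (5, 5(n-1)) for delay and interaction.  Partial eta
   squared is SS_effect / (SS_effect + SS_error).  Uncorrected df are the
   default (matching how such designs are conventionally reported);
   Greenhouse-Geisser epsilon correction is available (`gg = TRUE`),
   computed from orthonormal contrasts of the subject x cell matrix.
5. **Per-delay contrasts.**  Paired t tests across participants on the
   ln-scale cell means, one per delay, reported with the ms-scale mean
   difference.  Unadjusted p-values by default, Holm available.  Whether a
   published per-delay comparison used post-hocs or paired tests is often
   unstated; paired t is our documented choice.

## Numerical and I/O conventions

* The EWMA is implemented with `stats::filter(..., method = "recursive")`;
  a naive loop is the independent test oracle.
* All times in CSVs are stored to 0.001 ms, and generators emit values
  already rounded to that precision, so `read(write(x))` is an exact
  identity.
* Every random draw happens inside a per-call seed scope that restores the
  caller's RNG state, so package calls never perturb a user's session RNG.
* Degenerate inputs fail loudly with the offending trial, participant,
  cell or CSV line named in the error.

## Problem sizes used in tests and reports

The shipped test-and-report configuration uses 1000 simulated taps for the
fusion-resolution bound, 1000-trial bench sessions for jitter recovery, and
a cohort of 18 participants over the full 432-trial schedule for effect
recovery -- matched to the sample size at which this paradigm is typically
analysed.  Calibration properties use 20 replicate cohorts (recovery bias)
and 200 reduced cohorts of 8 participants and one block (null rejection
rate); these sizes give sampling error comfortably below the tolerances
asserted, while keeping the whole suite fast enough to run habitually.

## Known limitations

* The simulators model timing, not signal realism: tap transients are
  stylized, the vibration motor's accelerometer signature is absent, and
  accelerometer noise is white Gaussian.
* Device profiles shipped with the package declare plausible synthetic
  latencies; conclusions about any *real* device require a real bench.
* The analysis implements the classical repeated-measures ANOVA only;
  mixed-effects or Bayesian alternatives are out of scope.
* Hardware-measured quantities (actual delivery accuracies of specific
  phone models, F statistics from human cohorts) are inherently outside
  what simulation can reproduce; the package targets the *machinery* and
  its calibration, and its tests assert exactly that.
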