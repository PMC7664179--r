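---
title: "Detecting gait events and quantifying method agreement in forward and backward treadmill walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gait events and quantifying method agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmark)
```

## The problem

A gait analysis stands or falls on the timing of two events per stride
and side: initial contact (IC), when the foot first touches the ground,
and terminal contact (TC), when it fully leaves it. On a treadmill these
can be timed indirectly either from optical motion capture (OMC) marker
kinematics or from foot-mounted inertial sensors (IMUs). Backward walking
(BW) is widely used in rehabilitation and sport, but the standard
detectors were designed for forward walking (FW): in BW the foot strikes
toe-first and leaves heel-last, the kinematic geometry mirrors, and the
accelerometer signatures are smoother. This package implements detectors
for both directions and the agreement statistics needed to decide whether
the two measurement routes are interchangeable, validated end to end on a
simulator with exact ground truth.

## Detection models

### Kinematic route

The detection signal is the anterior–posterior (AP) displacement of a
foot marker relative to the pelvis,

$$d(t) = s\,\big(x_{\text{foot}}(t) - \bar x_{\text{pelvis}}(t)\big),$$

where $\bar x_{\text{pelvis}}$ is the centroid of the four pelvis markers
(left/right anterior and posterior superior iliac spines) and
$s \in \{+1,-1\}$ orients the lab axis so positive means "foot ahead of
the pelvis". The centroid stands in for a model-based pelvis segment; for
event *timing* the difference is a near-constant offset, which extrema
detection ignores. In FW the foot is farthest forward at IC (maxima of
$d$) and farthest back at TC (minima); in BW the labels swap exactly. By
default IC is taken from the marker on the foot region that strikes first
(heel in FW, toe in BW) and TC from the region that leaves last, both
configurable, including a single-marker mode.

### Inertial route

FW: impact transients make the vertical heel acceleration (H.ACC.Z) peak
at heel strike, so its smoothed maxima are IC; the heel sagittal angular
velocity (H.GY.Z) has its stride minimum around toe-off, so its smoothed
minima are TC. The source description of this rule lists "maxima and
minima" against "heel strikes and toes-off" across two channels; we read
it distributively (ACC maxima → IC, GY minima → TC), the only pairing
consistent with impact mechanics, and flag that interpretation here.

BW: maxima of the vertical toe acceleration (T.ACC.Z) are IC. TC uses a
run rule: with threshold $\theta = \mu - k\,\sigma$ ($k = 1$ by default)
computed from the mean and sample SD of the whole trimmed, filtered
record, every maximal run of consecutive samples below $\theta$ lasting
at least `min_run` (default 10 ms) contributes exactly one TC — the
run's first local minimum, or its earliest global-minimum sample if the
run is monotone. Two choices deserve note. First, the threshold is
anchored at the channel mean, not at a raw value of $-\sigma$: a
"one SD below the channel" rule is only meaningful relative to the
channel's own location, and anchoring at the mean makes it invariant to
constant offsets such as gravity. Second, $\sigma$ is computed per trial
over the trimmed record; a per-speed-segment SD would be an alternative
had the trial mixed speeds.

### Preprocessing

The standard chain, applied per channel before detection: kinematic and
accelerometer channels through a first-order low-pass Butterworth at
10 Hz; gyroscope channels through a first-order 0.001–5 Hz band-pass;
displacement and the FW heel channels additionally smoothed with an
order-3, 51-sample Savitzky–Golay filter (the smoothing window for the
inertial FW channels is not separately standardized, so it defaults to
the same 51 samples, configurable). The first and last second of every
record are then discarded so edge transients and gait initiation never
reach the detectors.

Butterworth filters are applied forward–backward (zero phase) by
default. Phase handling matters here more than usual: a causal
first-order low-pass at 10 Hz delays its output by ~16 ms at low
frequency, which would shift one method's events en bloc and masquerade
as between-method bias. The zero-phase pass has no group delay (the
package verifies a symmetric pulse stays centered) at the cost of
squaring the magnitude response; a causal mode is retained
(`zero_phase = FALSE`) for sensitivity analysis. Each directional pass is
initialized at the filter's steady state for the first sample value, so
the 0.001 Hz band-pass edge — whose start-up transient would otherwise
outlast a 30 s trial — maps constants to zero immediately (DC gain below
1e-3 by contract, with no NaN/Inf output).

### Peak engine

All detectors share one extremum finder. Candidate local extrema
(plateaus resolved to their earliest sample) are gated by topographic
prominence of at least `min_prominence` (default 0.1) times the
channel's robust amplitude (95th − 5th percentile), then thinned
tallest-first so retained extrema are at least `min_separation` apart,
ties toward the earlier sample. `min_separation` defaults to half the
dominant stride period, estimated as the earliest strong local maximum of
the channel autocorrelation between 0.3 and 3 s — "earliest strong"
rather than "global" because stride-time jitter occasionally lets the
two-stride harmonic edge out the one-stride peak, and an octave error
there would halve the detected cadence. These defaults were chosen to
suppress noise extrema at the slowest BW speeds without merging strides
at the fastest FW speeds; both are overridable everywhere.

## Agreement analysis

Two event series are compared per event kind and side. Pairing is greedy
nearest-neighbor under a tolerance (default 100 ms, comfortably above
realistic between-method errors), one-to-one and order-preserving;
unmatched test events are redundant detections, unmatched reference
events omissions. Differences follow the fixed convention
$d_i = t_{\text{test}} - t_{\text{ref}}$ (positive = test late); the
convention is arbitrary but documented, since the source literature does
not state one.

From the pairs we compute the mean absolute difference (ms, mean ± SD)
and Bland–Altman statistics: bias $\bar d$ and 95% limits of agreement
$\bar d \pm 1.96\,\mathrm{SD}(d)$, in the plain single-level form —
strides are treated as independent, with no repeated-measures
correction, matching how pooled-stride agreement tables are normally
built. Stride times (consecutive same-kind, same-side event intervals)
from the two methods feed an intraclass correlation. We use ICC(2,1) —
two-way random effects, absolute agreement, single measures — because
two methods measuring the same physical quantity must be penalized for
systematic offsets; a consistency form is available by flag. Confidence
intervals follow the McGraw–Wong variance-component F-quantile
construction, and estimates are banded as poor (< 0.5), moderate
(0.5–0.75), good (0.75–0.9) and excellent (> 0.9), boundaries assigned
to the lower band. A perfectly agreeing table (zero residual and rater
variance) returns ICC 1 with a degenerate unit interval rather than an
undefined ratio. FW–BW comparisons of absolute differences use the
Mann–Whitney U test: exact by full enumeration when
$\min(n_1,n_2) \le 8$ and $n_1 n_2 \le 64$ (the enumeration definition
remains exact under ties), otherwise the tie-corrected normal
approximation with continuity correction. No multiplicity correction is
applied across the handful of comparisons reported.

Whether left and right strides should be pooled is a study-design
question; `agreement_report(pool_sides = FALSE)` keeps sides separate
(matching never crosses sides either way). ICC stride pairing uses
consecutive *matched* events, so an isolated missed event merges two
strides for both methods symmetrically rather than desynchronizing the
pairing.

## The simulator

`simulate_trial()` generates the statistical structure the detectors
assume, with exact ground truth:

* **Stride times** $T_k \sim \mathcal N(\mu, \sigma^2)$ truncated at
  $\mu \pm 3\sigma$ (defaults: FW 1.05 ± 0.03 s, BW 1.30 ± 0.05 s).
  IC times accumulate the $T_k$ exactly; $TC_k = IC_k + c\,T_k$ with
  duty factor $c = 0.6$, the typical stance fraction of walking. The
  truncated-normal model (rather than a gait-phase oscillator) keeps
  ground-truth stride statistics analytic, which the ICC recovery checks
  exploit.
* **Displacement** is a train of symmetric lobes, $+A$ at each IC and
  $-A$ at each TC (signs flipped in BW), amplitude
  $A = v\,c\,\mu/2$ from belt speed $v$. Symmetry is the load-bearing
  property: each lobe is even about its event, so the zero-phase filter
  chain cannot displace the extremum, and the lobe SD (a fixed quarter
  of the smaller inter-event gap) keeps the 51-sample smoother's window
  from reaching asymmetric territory. A belt-realistic sawtooth (linear
  stance drift) was rejected deliberately: its duty-factor asymmetry
  biases any smoothed extremum by 15–20 ms, which would contaminate the
  simulator's timing contract that channel extrema coincide with truth
  events. This is the main realism concession, and it means the
  simulator cannot probe the (real) smoothing-induced bias of kinematic
  detection on asymmetric waveforms.
* **H.ACC.Z** carries a symmetric exponentially damped cosine (8 Hz,
  50 ms decay, amplitude 2 g) centered at each IC over a 1 g baseline;
  **H.GY.Z** is a smooth stride-periodic waveform with a Gaussian
  100 deg/s trough at each TC; **T.ACC.Z** has a positive Gaussian
  transient at IC and a smooth negative dip (default depth 2 g, ~3×
  the channel SD) centered at TC, guaranteed to cross the run-rule
  threshold every stride. Transients are centered rather than strictly
  causal for the same symmetry reason as the displacement lobes.
* **Noise** is white Gaussian per channel (defaults 2 mm marker, 0.05 g
  accelerometer, 1 deg/s gyroscope); left and right sides are simulated
  independently with a small stagger, since every detector and statistic
  here operates per side.

What the simulator does *not* emulate: soft-tissue artifact and marker
occlusion, sensor drift and bias walk, double-support biomechanics,
asymmetric or pathological gait, overground (non-treadmill) kinematics,
and the causal shape of real impacts. Passing tests therefore certify
the algorithmic pipeline — filters, peak logic, matching, statistics —
under the stated signal model, not detector accuracy on real recordings.

`regime_configs()` reproduces a two-condition, three-speed treadmill
protocol: FW at 1.12/1.34/1.56 m/s, BW at 0.42/0.54/0.66 m/s, stride
time scaling mildly with speed ($T \propto v^{-1/2}$), and stride counts
apportioned so the full-scale battery totals ≈1550 FW and ≈1321 BW
strides; a scale flag shrinks the battery for desk-size runs (the test
suite and acceptance script use `scale = 0.05`, ≈150 strides, which
keeps the full end-to-end battery under ten seconds on one core).

## Numerical choices and degenerate inputs

* Stream alignment trusts the shared trigger origin ($t = 0$); no
  cross-correlation alignment is attempted, and the 100 Hz and 1000 Hz
  grids are never merged — comparisons happen on event times in seconds.
  Event times are the timestamp of the identified sample (half-open
  sample convention), so OMC timing is quantized at 10 ms and IMU timing
  at 1 ms.
* File readers reject non-monotone or irregular time grids (tolerance
  1 µs) and any disagreement with the declared rates; units are declared
  in the config, never inferred or rescaled.
* Extremum ties (plateaus) resolve to the earliest sample; matching ties
  resolve to the earlier test event; both rules make reruns
  deterministic.
* Empty detections on non-degenerate traces warn but return empty event
  series, so batch runs degrade gracefully; zero-variance channels make
  the BW run rule's threshold undefined and raise an error instead.
* Bland–Altman needs ≥ 2 pairs, the ICC ≥ 3 strides and non-zero total
  variance; below those sizes the report carries NA statistics with a
  warning rather than failing the whole battery.
* Battery runs derive per-trial seeds from the master seed and embed no
  timestamps in their JSON summaries, so a rerun with the same seed is
  byte-identical.

## Known limitations

Detection accuracy on real data will be worse than on the simulator in
ways the model cannot show (soft tissue artifact, sensor placement,
pathological waveforms). The per-trial SD in the BW run rule assumes
speed is constant within a record. The ICC treats pooled strides as
independent targets, inflating precision when strides are autocorrelated.
And the kinematic detector inherits the documented sensitivity of
smoothed-extremum methods to waveform asymmetry; on real data, pairing it
with a force-plate reference before trusting absolute timing remains good
practice.

## A complete run

```{r battery, eval = FALSE}
bat <- run_battery(seed = 1, scale = 0.05)
tidy(bat)       # one row per condition x event kind
bat$comparisons # FW vs BW Mann-Whitney on |differences|
```
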