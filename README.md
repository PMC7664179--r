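# gaitmark

Gait event detection and between-method agreement analysis for forward
(FW) and backward (BW) treadmill walking, with a synthetic gait simulator
for end-to-end validation.

Backward walking is increasingly used in neurologic and orthopedic
rehabilitation, but the standard indirect methods for timing gait events —
optical motion capture (OMC) marker kinematics and foot-mounted inertial
measurement units (IMUs) — were developed and validated for forward
walking. `gaitmark` implements both families of detectors for both walking
directions and the full statistical machinery for asking whether two
methods can be used interchangeably. It is aimed at movement scientists
and biomechanics engineers who need reproducible event detection from
plain columnar exports, plus a ground-truth simulator to characterize
detector behavior under controlled noise and stride variability.

## Methods in the package

**Event definitions.** Initial contact (IC) is the instant the foot first
touches the ground (heel strike in FW, toe strike in BW); terminal contact
(TC) is the instant it fully leaves the ground (toe-off in FW, heel-off in
BW).

**Kinematic (Zeni-style) detector.** The anterior–posterior displacement
of a foot marker relative to the pelvis centroid,
`d(t) = s · (x_foot(t) − x̄_pelvis(t))` with `s = ±1` the forward sign, is
low-pass filtered (first-order Butterworth, 10 Hz) and Savitzky–Golay
smoothed (order 3, 51 samples). In FW, maxima of `d` are IC and minima are
TC; in BW the labels swap.

**Inertial detectors.** In FW, maxima of the smoothed vertical heel
acceleration (H.ACC.Z, impact transients) give IC and minima of the
smoothed heel sagittal angular velocity (H.GY.Z, band-passed
0.001–5 Hz) give TC. In BW, maxima of the vertical toe acceleration
(T.ACC.Z) give IC, and TC uses a run rule: with threshold
`θ = mean − 1·SD` over the trimmed record, each below-θ run lasting at
least 10 ms yields one TC at its first local minimum.

**Agreement statistics.** Events from two methods are paired one-to-one by
greedy, order-preserving nearest-neighbor matching within a 100 ms
tolerance; unmatched events are counted as identification errors. For the
paired differences `d_i = t_test − t_ref`, the package reports the mean
absolute difference (ms, mean ± SD), Bland–Altman bias and 95% limits of
agreement `bias ± 1.96·SD(d)`, the two-way random-effects
absolute-agreement single-measures ICC(2,1) of stride times with its
McGraw–Wong 95% CI and conventional bands (poor < 0.5, moderate
0.5–0.75, good 0.75–0.9, excellent > 0.9), and Mann–Whitney U tests
(exact by enumeration for small samples, tie-corrected normal
approximation otherwise) for FW-vs-BW comparisons of absolute differences.

**Simulator.** `simulate_trial()` generates marker (100 Hz) and IMU
(1000 Hz) streams with truncated-normal stride times and known event
times: symmetric displacement lobes whose extrema sit exactly on the truth
events, damped-cosine impact transients at IC, a stride-periodic angular
velocity minimum at TC, and a below-threshold dip before each BW terminal
contact — all with configurable amplitudes and Gaussian noise.

## Worked example

```r
library(gaitmark)

sim <- simulate_trial(sim_config("BW", n_strides = 30, seed = 11))
omc <- detect_events(sim$trial, method = "omc")   # kinematic reference
imu <- detect_events(sim$trial, method = "imu")   # inertial test method
rep <- agreement_report(omc, imu)
tidy(rep)
#> # A tibble: 2 × 16
#>   condition kind  side       n mad_ms mad_sd_ms bias_ms loa_low_ms loa_high_ms
#>   <chr>     <chr> <chr>  <int>  <dbl>     <dbl>   <dbl>      <dbl>       <dbl>
#> 1 BW        IC    pooled    60   2.37      1.69   0.467      -5.19        6.12
#> 2 BW        TC    pooled    60   2.82      1.44  -1.05       -6.94        4.84
#>     icc icc_ci_low icc_ci_high n_strides icc_class n_unmatched_ref
#>   <dbl>      <dbl>       <dbl>     <int> <chr>               <dbl>
#> 1 0.993      0.987       0.996        58 excellent               0
#> 2 0.981      0.969       0.989        58 excellent               0
```

Reading the output: across 60 matched BW initial contacts the inertial
method differs from the kinematic one by 2.4 ms on average (|difference|),
with a +0.5 ms bias and 95% of differences expected between −5.2 and
+6.1 ms; stride-time agreement is excellent (ICC 0.993, CI 0.987–0.996),
and no event was missed or detected redundantly. `glance(rep)` condenses
this to one row; `autoplot(rep$pairs$IC.pooled)` draws the Bland–Altman
plot.

`run_battery()` wires the whole study design together — two conditions ×
three treadmill speeds, both detectors, pooled agreement per condition and
event kind, FW-vs-BW Mann–Whitney comparisons — and writes a deterministic
JSON summary. A command-line wrapper for simulate/detect/agree/battery is
installed at `inst/scripts/gaitmark`.

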