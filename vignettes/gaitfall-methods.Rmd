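---
title: "Methods: gait-phase detection, phase-gated perturbation, and waveform statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait-phase detection, phase-gated perturbation, and waveform statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfall)
```

This vignette is the package's own account of its models and the design
choices behind them: what is computed, under which assumptions, which
knobs matter, and what the synthetic validation does and does not show
about real data.

## The continuous gait phase

Walking is treated as a limit-cycle oscillation of the hip: over a stride
the sagittal hip flexion angle is approximately sinusoidal and its angular
velocity approximately the quadrature component, so the state
`(flexion, velocity)` traces a closed loop — the phase portrait — once per
gait cycle. The angular position along that loop is the *continuous gait
phase*, an angle in `(-pi, pi]` that advances by `2*pi` per stride. The
more circular the portrait, the more uniformly the phase advances in time,
which is what makes it usable as a trigger clock.

`estimate_phase()` computes it causally, sample by sample:

1. **Bandpass.** Both channels pass through a single-pass (forward-only)
   second-order Butterworth bandpass, cutoffs 0.4 and 3 Hz. The band
   brackets stride frequencies from very slow (0.67 Hz at 40 strides/min)
   to fast (1.17 Hz at 70) walking with room for drift, removes the DC
   flexion offset, and suppresses impact transients. Causality matters:
   the platform must act on the estimate in real time, so no zero-phase
   (forward–backward) filtering is available here.
2. **Amplitude normalization.** Each channel is scaled by a running robust
   amplitude — the 90th percentile of the absolute value over the current
   window. A robust quantile resists spikes better than the maximum and
   tracks slow amplitude drift; the price is a sub-percent scale error on
   non-integer numbers of periods, which bounds the noiseless accuracy of
   the estimator at roughly `1e-3` rad rather than machine precision.
3. **Unit-sine fit.** The normalized pair is fitted to a unit-magnitude
   sine wave, `flexion ~ sin(2*pi*f*t + phi)` and
   `velocity ~ cos(2*pi*f*t + phi)` *jointly*, by Levenberg–Marquardt
   (`minpack.lm::nls.lm`, analytic Jacobian) over the two parameters
   `(f, phi)`. The joint fit is a deliberate choice: fitting the channels
   separately can return inconsistent phases, whereas shared parameters
   make the subsequent `atan2` well defined by construction. The window
   spans 1.5 estimated fundamental periods — long enough to condition the
   frequency estimate, short enough to track cadence changes within a
   stride or two — and each fit is warm-started from the previous one.
   Non-convergent fits (flat windows, dropouts) are flagged and the
   previous fit is retained.
4. **Phase extraction.** The phase is the four-quadrant inverse tangent of
   the fitted flexion over the angular velocity. Evaluated on the fitted
   unit sine this is exactly the model phase `2*pi*f*(t - t_ref) + phi`;
   the raw `atan2` of the normalized filtered samples is available as
   `method = "atan2"` and differs only through harmonic content and noise.
5. **Filter-lag compensation.** The causal bandpass shifts both channels
   by its phase response `Arg(H(f))` at the stride frequency; since the
   shift is common to both channels it appears as a pure offset in the
   estimated phase and is subtracted using the designed coefficients
   (`compensate_lag = TRUE`). On noiseless single-harmonic input this
   makes the estimator agree with the analytic phase to the normalization
   floor described above.

Two implementation details depart from a literal every-sample refit. The
sine fit is refreshed every `refit_interval_s` (default 0.05 s, sixteen
times per stride at normal cadence) and the phase between refits is
advanced at the fitted frequency; with parameter drift far slower than the
refit interval, the phase trajectory is indistinguishable from an
every-sample refit while costing two orders of magnitude less. Second, the
initial frequency seed comes from zero-crossing intervals of the filtered
velocity over the first four seconds — cheap, causal, and only needed to
size the first window.

**Warm-up.** No phase is emitted before one window plus two fundamental
periods (`warmup_periods = 2`): the filter transient at the 0.4 Hz edge
decays over a few seconds, and early fits would otherwise chase it.
Samples before warm-up carry `NA`.

**Heading.** A single thigh IMU only measures sagittal flexion while the
body's sagittal plane is fixed; turning leaks heading change into the
flexion channels. The torso-referenced correction subtracts the torso yaw
excursion (and its rate) from the flexion (and velocity) channels —
exactly the inverse of the additive leakage model used by the generator.
It is the identity under constant heading, including constant offsets.

**Discretization.** The interval `(-pi, pi]` is split into twenty equal
half-open bins of width `pi/10`; bin 0 starts at `-pi`, the single point
`pi` closes bin 19, and out-of-range inputs are wrapped, never rejected.
One segment is assigned to each fall type as its trigger.

### Where phase zero sits

Nothing in the phase definition pins a particular gait event to a
particular phase value. The package adopts the generator's convention —
left heel strike at wrapped phase `pi/2`, toe-off 60% of a cycle later —
and *calibrates* the default trigger segments against it: mid-swing
detection (cycle fraction 0.80, segment 11) gates the two trip types and
early stance (fraction 0.02, segment 15) gates the slip. On real hardware
this mapping is a calibration constant per subject population, which is
why it lives in `fall_config()` rather than in code.

## Trigger semantics

`run_control_loop()` fires on the *entry edge*: the first sample at or
after the request where the segment stream transitions into the target
segment. Level semantics would fire immediately on a request issued while
the phase already happens to be inside the target segment — typically
mid-segment and up to a twentieth of a cycle late relative to the intended
gait event. Entry-edge semantics instead defer to the next cycle. Each
request yields at most one event, carrying the activation duration of its
fall type (400 ms lowering, 250 ms skipping and slip, < 250 ms elevating;
the elevating entry ships configurable but untested, since eliciting it
reliably requires per-subject tuning). Mechanism cable tensions are
carried as metadata only (`mechanism_forces()`); no cable, spring or brake
dynamics are simulated.

## The subject follower

The follower holds the depth camera 50 cm behind the subject. The
observation model is a pinhole camera (defaults: 86 degrees horizontal
field of view, 848 columns, 30 Hz) observing the subject as a point: `d`
is the depth along the platform's forward axis and `theta` the angle of
the subject's mean pixel column off that axis, recovered through the
camera's angular resolution with optional pixel quantization. Two
decoupled PD loops map the errors to a forward-speed and a turn-rate
command, mixed into differential wheel speeds
(`left = v - w*track/2`, `right = v + w*track/2`; a pure turn spins in
place). Integration is forward Euler at the camera rate — adequate because
the closed loop is first order and heavily damped.

The gains are not measured constants; they were chosen by discrete-time
pole placement so that the linearized distance loop
(`e_{n+1} = (1 - dt*kp - kd) e_n + kd e_{n-1}` at `dt = 1/30`) is
overdamped and settles within a few seconds without overshoot
(`kp_d = 2 s^-1`, `kd_d = 0.2`; turning loop `kp_th = 1.5`,
`kd_th = 0.1`). Since the commands are velocity-level and the loop is
proportional on the error, a stationary subject gives zero steady-state
error; a subject walking at speed `v` is tracked with the closed-form lag
`v / kp_d` behind the setpoint. If the subject leaves the field of view
the last command is held for 0.5 s and the platform then stops — a
safety-consistent policy chosen here, not a measured behaviour.

## Stride processing

Offline kinematics are filtered with a dual-pass (forward–backward)
first-order Butterworth low-pass at 6 Hz: the two passes square the
magnitude response and cancel the phase, so events and waveforms are not
shifted in time. The implementation pads by odd reflection before each
pass so that a constant passes through unchanged to the edges.

Strides are bookended by consecutive heel strikes of one leg, each
annotated with its single interior toe-off; strides without exactly one
toe-off are dropped and counted. Each stride is resampled by linear
interpolation onto 101 nodes — the field's convention for gait-cycle
waveforms, giving integer percent positions — with stance mapped to nodes
0–60 and swing to nodes 60–100 *regardless of the raw stance/swing time
split*. Node 60 is the raw signal interpolated at the exact toe-off
instant; endpoints are likewise exact, so normalization is idempotent.
Linear interpolation suffices because the signals are already band-limited
at 6 Hz. Left and right legs are processed and analysed separately
throughout. For perturbation trials, only gait cycles whose half-open
`[heel strike, next heel strike)` interval contains a trigger firing are
retained for analysis; unperturbed conditions keep all complete strides.
Gait events are primary inputs (from the generator's ground truth, or
motion capture in a real deployment); a fallback detector based on heel
forward-velocity thresholds exists for synthetic data only, since the
detection rule of a real system is a lab-specific choice.

## Waveform statistics

A dataset is an array `subjects x conditions x 101 nodes` of
time-normalized waveforms. At each node independently, a one-way
repeated-measures ANOVA partitions
`SS_total = SS_conditions + SS_subjects + SS_error` and forms
`F = (SS_cond/(k-1)) / (SS_error/((k-1)(n-1)))` — subjects are blocks, so
between-subject variance never inflates the error term, and the F value is
the mean condition effect per unit of error variance. Sphericity is
assumed, not corrected: the analysis mirrors the plain repeated-measures
form, and the permutation threshold provides a distribution-free check
that does not rest on sphericity at all. For per-subject analyses the
replicates are that subject's trials and the design is a one-way
between-trials ANOVA with `N - k` error degrees of freedom; a single
subject has no subject factor to block on.

**Thresholding.** Testing 101 correlated nodes at `alpha = 0.05` each
would not control the familywise rate. The critical height is instead set
so that a *smooth random field* of the same smoothness would be expected
to produce a suprathreshold cluster in only 5% of null datasets: the
expected Euler characteristic of the F field,
`E[EC](u) = P(F > u) + R * rho_1(u)`, with resel count
`R = (Q - 1)/FWHM` and `rho_1` the one-dimensional EC density of an F
field, is solved for `E[EC](u) = alpha`. The implementation's `rho_1`
satisfies the `t^2 = F` consistency identity at one numerator degree of
freedom, which is also enforced by test. The field smoothness is estimated
from the normalized ANOVA residual gradients (ratio of gradient variance
to residual variance, converted to the FWHM of the Gaussian kernel that
would produce it on white noise); the estimator is scale-invariant, has a
discrete floor of about 2.3 nodes on white residuals, and recovers known
smoothness within 15% over FWHM 5–25 on 101 nodes. The threshold is
monotone decreasing in FWHM and never below the pointwise `1 - alpha`
quantile; with one denominator degree of freedom the t-field density does
not decay and no finite threshold exists, which the code reports as an
error rather than silently returning something.

**Permutation check.** The nonparametric counterpart permutes condition
labels *within subject* — the exchangeability unit of a repeated-measures
design — and takes the `1 - alpha` quantile of the maximum-over-nodes F.
Designs with few arrangements fall back to exact enumeration. On matched
smooth null data the two thresholds agree within 10%, and both control the
familywise error within the binomial 95% interval around 0.05 over 1000
null datasets (the calibration is re-run by the test suite and the
acceptance script at exactly that size).

**Reporting.** Suprathreshold clusters are maximal runs of nodes strictly
above the threshold, reported in percent of gait cycle. The colour map
bins the excess `F - F_crit` into unit-F intervals: since F is effect per
unit mean square of error, one bin step is one MSE of effect — this is the
package's reading of "intervals of one MSE", chosen over binning raw MSE
units because the latter is not monotone in evidence; the reading is a
documented choice, not an assertion about anyone's intent. Post-hoc paired
t fields are computed per condition pair and thresholded by the t-field
analogue at `alpha / (number of pairs)` (Bonferroni), two-tailed. No
multiplicity correction is applied across joints or trial types: each
joint and each fall type is assessed as a separate outcome. The four-row
report stacks, per joint: condition means with SD clouds; the F field with
its dotted threshold and grey cluster shading; the colour map; and
per-subject significance strips, with the stance/swing divider at node 60
and the perturbation-onset marker at its configured node. With no
per-subject results the figure degrades to three rows.

## What the generator emulates — and what it does not

`generate_walk()` produces hip flexion as a two-harmonic sinusoid (default
30 degrees about a 5 degree offset, second harmonic at 0.15 of the
fundamental) with the angular velocity as its analytic derivative plus
independent Gaussian noise on each channel — the simplest model consistent
with filtered IMU output. The second harmonic is deliberate: it makes the
phase portrait non-circular, as real hip kinematics are, so the estimator
is validated on the distortion it will actually face. Speed presets follow
healthy adults (slow 40 strides/min at 0.90 m/s, normal 55 at 1.25, fast
70 at 1.60). Events are tied to fixed truth-phase values with stance
exactly 60% of the stride; knee and ankle trajectories are periodic
Gaussian-bump templates with the canonical double-bump knee shape; heel
positions advance by one stride length per cycle through a raised-cosine
swing bump, which makes the mean step length exactly
`speed / (2 * stride_frequency)`.

Perturbation responses are *stylized kinematic shapes*, not dynamics:
brake falls hold the ipsilateral joint trajectories for the activation
duration and then blend into a lowered-leg / widened-contralateral-swing
recovery; the slip adds a forward velocity impulse with a flat-foot hold
and shortens the contralateral recovery step to roughly a third of normal.
There is no musculoskeletal model, no ground contact, no ground-reaction
forces or EMG, and no 3D marker synthesis. Passing tests therefore
demonstrate that the *pipeline* — estimation, triggering, segmentation,
statistics — behaves correctly on signals with realistic spectral and
trial structure; they say nothing about biofidelity of fall kinematics,
and real IMU artefacts (soft-tissue wobble, mounting slip, magnetometer
drift) are outside the noise model.

`generate_null_dataset()` builds the calibration datasets: Gaussian white
noise convolved with a Gaussian kernel of stated FWHM (padded so the
variance is exactly stationary, then scaled to unit pointwise variance),
plus a per-subject constant offset (SD 0.3) that is exchangeable across
conditions — present so that the repeated-measures blocking is actually
exercised, invisible to the F field by construction.

## Numerical choices and degenerate inputs

* Wrap convention `(-pi, pi]` everywhere; angles in degrees at I/O,
  radians internally for phase.
* Non-uniform IMU timestamps (more than 5% jitter) are linearly resampled
  to the nominal rate before filtering; the 333 Hz rate is a mean, not a
  guarantee.
* Bins, strides and cluster runs use half-open intervals; a node exactly
  at the threshold is *not* significant; a trigger exactly on a stride
  boundary belongs to the starting stride.
* Degenerate fits (flat windows) return a non-convergence flag, never an
  exception; constant residuals yield infinite smoothness with a warning;
  an onset segment never reached yields an unmodified trial with a
  warning; a timed-out trigger request returns `NULL` with a warning.
* The RFT bracket expansion guards against the one-denominator-df
  degeneracy described above.
* All generators and the permutation scheme are pure functions of their
  seed and restore the caller's RNG state.

## Problem sizes used in validation

The test suite and acceptance script run at sizes chosen to make the
statistical checks sharp while staying comfortably desk-scale: walking
trials of 10–16 s at 333 Hz for estimator accuracy (circular RMSE
criterion 0.3 rad, about a tenth of a discretization segment in standard
deviation terms); 1000 null datasets of 7 subjects x 3 conditions x 101
nodes at FWHM 15 for familywise-error calibration of both thresholds (500
permutations per dataset for the nonparametric one); 25 datasets with 1000
permutations each for the threshold cross-validation; 20 s of simulated
following for the setpoint check. The demo pipeline (`run_config()`)
defaults to 3 subjects with two trials per condition and 10 s trials; the
full protocol shape — 7 subjects, five trials of each walking condition,
three of each fall type — is reachable by raising the counts.

## Known limitations

* The estimator's accuracy floor (~1e-3 rad noiseless) is set by the
  robust amplitude normalization; an adaptive integer-period normalizer
  would lower it but complicate causality.
* RFT thresholds assume a smooth Gaussian field; at very small denominator
  degrees of freedom or very rough fields the permutation threshold is the
  more trustworthy of the pair.
* The follower model is kinematic: no motor dynamics, wheel slip, or
  payload inertia, so gain settings transfer to hardware only as starting
  points.
* Slip trials can end without a demarcating heel strike; such cycles are
  closed at trial end and flagged, a convention rather than a measurement.
* The segment-to-gait-event mapping is calibrated against the generator's
  phase convention and must be recalibrated for any other phase-zero
  convention.
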