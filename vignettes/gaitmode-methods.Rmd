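---
title: "Gait-mode recognition from a foot-mounted IMU: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-mode recognition from a foot-mounted IMU: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gaitmode` classifies each walking step as level-ground, ascent, or descent
from a single foot-mounted inertial sensor and two foot switches, causally
and continuously, for use in swing-phase control of powered ankle-foot
orthoses. This vignette is the package's account of the science: the signal
model, the classifier, the decision rule, the evaluation metrics, the
synthetic data used to exercise everything, and the choices made where the
design was genuinely open.

## Signal model

The sensor stream carries, at a fixed rate `fs` (200 Hz by default), the
body-to-world orientation quaternion, the body-frame accelerometer vector,
and two binary force-sensitive-resistor (FSR) channels under heel and toe.
Two derived signals feed the classifier.

**Vertical foot velocity.** The world-frame vertical acceleration
`a_z` is integrated after subtracting gravity (`g` = 9.81 m/s²). Raw
integration drifts without bound, so a zero-velocity update (ZUPT) exploits
the fact that the foot is stationary in mid-stance: whenever

```
|a_z − g| < ε_g
```

holds for at least `min_dwell` consecutive samples, those samples are
zero-velocity instances and the velocity estimate is re-anchored to exactly
zero there. Two corrections are available: `reset` discards the accumulated
value at the instance, while the default `linear_detrend` subtracts the
linear ramp over the interval since the previous instance, which attributes
the accumulated error to a constant bias — the standard ZUPT practice, and
exact when the error really is a constant bias. Samples before the first
instance are anchored by back-propagating the first correction. If noise
prevents the acceleration rule from firing during some stance period, the
midpoint of the heel-and-toe both-ON interval is used as a fail-safe anchor,
so every stance period anchors the velocity at least once.

**Foot pitch.** The sagittal segment angle is extracted from the quaternion
by the aerospace ZYX sequence, `θ = asin(2(q_w q_y − q_z q_x))`, with the
argument clamped to `[−1, 1]` near gimbal degeneracy. The convention is
toe-up positive, rotation about the mediolateral (y) axis. Any standard
pitch extraction consistent with that convention would do; the package
declares this one and uses it both in analysis and in the synthetic
generator, so the two are consistent by construction.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `eps_g` | tuned | m/s² | zero-acceleration band half-width |
| `min_dwell` | 5 | samples | dwell needed before an instance counts (25 ms at 200 Hz), rejects single-sample noise crossings |
| `drift_mode` | `linear_detrend` | — | drift attribution between anchors |
| `epsilon` | 0.02 | s | output-filter time constant |
| `lambda12 : lambda21` | 1.0 : 0.5 | — | asymmetric misclassification losses |
| `n_delays` | 6 | samples | tapped delays per input signal |
| `n_hidden` | 10 | neurons | hidden-layer size |

`ε_g` is not a constant of nature: it depends on sensor noise and on how
cleanly the wearer's stance is stationary. `tune_eps_g()` scans 30
log-spaced candidates in [0.01, 2.0] m/s² from the largest down and keeps
the largest value whose detections (with the dwell rule) all fall inside
known stance windows — FSR-derived any-contact intervals in the training
pipeline. Scanning from the top biases toward sensitivity; if no candidate
qualifies, the grid minimum is returned with a warning flag and the
fail-safe carries the anchoring.

## The network

The input vector concatenates the 6 most recent samples of `v_z` and the 6
most recent of `θ` (newest last, 12 elements), z-scored per element with
training-set statistics stored in the model — the two signals live on
different scales (m/s vs degrees) and the standardization keeps the training
problem well conditioned. At the stream start the delay line is padded by
repeating the first sample, and such vectors are flagged.

The network is 12–10–3: log-sigmoid hidden layer, linear output layer. The
three outputs target the coding Ascent `(1,0,0)`, Level `(0,1,0)`, Descent
`(0,0,1)`, Undetermined `(0,0,0)`.

Training is Levenberg–Marquardt on the Gauss–Newton approximation of the
regularized cost `E = α E_D + β E_w` (note the convention: `α` multiplies
the data misfit and `β` the weight penalty). The damping `μ` starts at 1e−3,
multiplies by 10 on a rejected step and by 0.1 on an accepted one, so the
cost at the current `(α, β)` never increases across accepted steps. After
each epoch `α` and `β` are re-estimated by the evidence framework adapted to
this parameterization: with `k` free parameters (163 here) and
`H = 2α JᵀJ + 2β I`,

```
γ = k − 2β tr(H⁻¹),    β = γ / (2 E_w),    α = (n − γ) / (2 E_D),
```

`γ` being the effective number of parameters and `n` the number of residual
components. Training stops on a gradient-norm floor (1e−7), a relative cost
decrease below 1e−8, exhausting `max_epochs` (300), or `μ` exceeding 1e10
without an acceptable step. Weights are initialized from a seeded uniform
±0.5 draw with Nguyen–Widrow row scaling; the seed is part of the training
configuration, so identical seed + data + configuration reproduce the model
bit for bit.

Two pragmatic choices deserve a note. First, training rows are decimated
(default: every 3rd sample) before the Jacobian is assembled: neighbouring
200 Hz samples are highly autocorrelated, so a stride-3 training set loses
essentially no information while shrinking the `3n × 163` Jacobian
threefold; classification always runs at the full rate. Second, initial
hyper-parameters are `α = 1`, `β = 0.005` — a weak prior toward small
weights that the evidence updates quickly overwrite.

## From network output to a mode decision

The raw outputs are noisy sample-by-sample, so each element passes through
the first-order filter `ε ẏ̄ + ȳ = y` with `ε = 0.02` s, discretized by the
exact exponential integrator for piecewise-constant input
(`ȳ_k = ȳ_{k−1} + (1 − e^{−1/(fs ε)})(y_k − ȳ_{k−1})`, `ȳ_0 = y_0`),
which is unconditionally stable and matches the continuous step response at
the sample instants exactly.

For each element the filtered training values form two classes — class 1
where the element's target is 0, class 2 where it is 1 — each modelled as a
Gaussian. The decision threshold `z_o` solves

```
λ12 p(z | w1) = λ21 p(z | w2)
```

which minimizes the expected risk under the loss matrix
`L = [[0, 1.0], [0.5, 0]]`: a false activation (class 1 called class 2)
costs twice a missed activation, a deliberately conservative detector. With
equal class SDs the solution is closed-form —
`z_o = (μ1+μ2)/2 + σ² ln(λ12/λ21)/(μ2−μ1)` — shifted above the midpoint for
`λ12 > λ21`. With unequal SDs the condition is a quadratic whose two real
roots are a risk minimum and a maximum; the root inside
`(μ1 − σ1, μ2 + σ2)` nearest the class-mean midpoint is the minimum and is
selected, with a midpoint fallback (and warning) for pathological
parameters. Class SDs are floored at 1e−3 so that a near-perfectly-separated
training fit cannot produce a degenerate density. A plain 0.5 threshold is
kept behind `naive_half = TRUE` for comparison; the risk-based thresholds
replace it by default.

Binarization maps element `k` to 1 when `ȳ_k ≥ z_o[k]` (ties to 1 — a
measure-zero event fixed for determinism), and the binary vector maps to a
mode by the target coding. Codings with two or three active elements are
not defined by the coding table and map to Undetermined; Undetermined
samples carry no mode and their resolution is left to the step level.

## Step-level evaluation

Gait cycles are segmented from the foot switches: heel strikes at debounced
OFF→ON transitions of the heel FSR (a new contact state must persist 10
samples), swing start at the last debounced ON→OFF transition of the toe FSR
before the next heel strike. A step's decision window is
`[swing_start, next_heel_strike)` — exactly the swing phase, where the two
input signals are informative. The predicted mode of a step is the label of
the longest run of identical determined samples in the window (ties to the
later run); the detection sample is the first sample from which the
prediction equals that mode and never reverts to a different determined
label within the window. The success rate is the percentage of steps whose
predicted mode equals the true mode; an Undetermined step prediction counts
as incorrect — the conservative reading, since an undecided controller is
still a failure to recognize the step. Detection delay is
`100 (detect − swing_start) / (next_hs − hs)` in percent gait cycle;
transition steps are those whose true mode differs from the previous
step's, and the reported mean delay averages correctly recognized transition
steps (a wrongly classified transition has no meaningful delay to the new
mode).

## The synthetic gait simulator

No subject recordings ship with the package, so `generate_trial()` /
`generate_study()` emulate the two collection protocols with full ground
truth: the stair scenario walks 3–4 level steps, 6 stair-ascent steps
(14 cm rise each), 3–4 level, a turn, 3–4 level, 6 stair-descent, 3–4
level; the ramp scenario walks 3–4 level, 8–10 up a 6-degree grade, a turn,
8–10 down, 3–4 level. Five synthetic subjects × three trials per scenario,
the first trial flagged for training — the study layout. Turns are modelled
as two slow steps labelled Level.

Per step, the swing-phase vertical trajectory is a minimum-jerk rise of
`+0.14` m (stair ascent), `−0.14` m (descent), `±stride_length · tan(6°)`
(ramp), or 0 (level), plus a smooth clearance arc (5 cm peak) whose value,
velocity, and acceleration vanish at the swing boundaries, so the emitted
acceleration is continuous; velocity and acceleration are the analytic
derivatives, and the swing spans the interval between the bounding stance
samples so the sampled kinematics are mutually consistent. The stance foot
is flat and stationary (`v_z = 0`, `a_z = g` exactly), heel contact from
heel strike to 75% of stance, toe contact from 15% of stance to toe-off.
Swing pitch superimposes, on a smooth interpolation between the stance
surface offsets (±6° on the ramp, 0 elsewhere), an early plantarflexion
lobe (toe-down push-off, −15° peak for level walking) and a sustained
mid-swing sweep: +25° (toe pulled up over the step edge) for stair ascent,
−25° for stair descent, ±15° on the ramp, +6° for level clearance. These
shapes are constrained by the protocol geometry (rise, grade, step counts)
and by the qualitative observation that foot pitch and vertical velocity
differ across modes; their exact amplitudes are the package's design, chosen
so the swing-phase class-conditional distributions of `(v_z, θ)` differ
between every mode pair by at least two pooled standard deviations — the
task is well-posed, not trivially easy, under the default noise.

Measurement noise is white: accelerometer SD 0.3 m/s², pitch SD 1°, chosen
so that `ε_g` genuinely needs tuning (the tuned values land around 0.1–0.3
m/s² across subjects) and the FSR fail-safe occasionally fires. Subjects
differ by seeded kinematic jitter (±10% stride time, stride length, and
profile amplitude), constant within a subject. Every trial is a
deterministic function of `(seed, subject, trial, scenario)`.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: orientation-estimation error beyond white pitch
noise (no gyroscope drift or attitude-filter transients), horizontal
kinematics and their leakage into `a_z` under imperfect orientation,
non-stationary stance (heel-roll and push-off force the real foot to move
through much of stance), FSR bounce and partial contacts, fatigue or
step-to-step variability beyond white noise, and any real inter-subject
variability — the jitter ranges are nominal. Perfect scores on synthetic
test trials therefore demonstrate the pipeline's internal correctness and
the method's behaviour under its own assumptions, not field performance.

## Study-scale results computed by this package

`scripts/acceptance.R` (and the acceptance test suite) run the full
synthetic study — 5 subjects × 3 trials × 2 scenarios at default noise,
training per subject on trial 1 and testing on trials 2–3, roughly 150
pooled level steps and 60–90 ascent/descent steps per scenario — and report
pooled per-mode success rates and mean transition-step detection delays.
These sizes keep a complete train-and-evaluate cycle for both scenarios
around a minute of CPU while leaving enough steps for stable percentages.

## Known limitations

* Orientation is taken as given per sample; there is no on-line attitude
  filtering, magnetometer fusion, or 3-D position tracking.
* The Gaussian two-class model for filtered outputs is an approximation;
  heavy-tailed or multimodal output distributions would call for different
  densities (not implemented).
* Training is subject-specific by default, mirroring the study design;
  pooling across subjects is possible by passing several trials to
  `train_gait_classifier()` but is not the tested configuration.
* The evaluation counts Undetermined step predictions as errors and averages
  delays over correctly recognized transition steps only; both choices are
  stated here because other conventions would change the reported numbers.
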