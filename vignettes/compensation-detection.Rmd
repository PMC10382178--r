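---
title: "Detecting compensatory movement from energy-based joint features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting compensatory movement from energy-based joint features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compsense)
```

## The problem

After a stroke, people often complete reaching and lifting tasks by
recruiting joints that healthy movement leaves largely quiet — leaning or
rotating the trunk instead of elevating the shoulder, hiking the shoulder
instead of extending the elbow. These *compensatory strategies* get the
task done but impede long-term recovery, so therapists want them detected
— ideally online, while the movement is happening, and with an indication
of *which* joint is compensating.

`compsense` implements a detection pipeline built on three ideas:

1. **Energy-based per-joint features.** Healthy movement is smooth and
   metabolically cheap; compensation redistributes effort across joints.
   For each analyzed degree of freedom (DoF) $j$ and time step $t$ the
   package computes four non-negative metrics from the joint kinematic
   trajectory $\{q_t, \dot q_t, \ddot q_t\}$ and dynamic trajectory
   $\{\tau_t\}$:
   jerk $|\dddot q_{t,j}|$ (movement smoothness), power
   $|\dot q_{t,j}\,\tau_{t,j}|$, effort $|\ddot\tau_{t,j}|$, and torque
   rate $|\dot\tau_{t,j}|$. With the default 10 DoFs (3 torso + 7
   dominant-arm) this gives a $10\times4$ feature matrix, flattened
   DoF-major to $\phi\in\mathbb{R}^{40}$.
2. **Cumulative averaging (CAE).** Instantaneous metrics are noisy and
   carry no history, so each feature at time $t$ is replaced by its
   running mean from the start of the current motion primitive — the
   Cumulative Averaged Energy feature. Motion primitives are delimited by
   rests of the end-effector, found as zero-crossings of the smoothed
   wrist-marker velocity.
3. **Interpretable linear classification.** A linear hyperplane
   $w\cdot\phi + b = 0$ separates the classes with the decision rule
   $w\cdot\phi+b < 0 \Rightarrow$ *Compensation*,
   $\geq 0 \Rightarrow$ *No Compensation* (healthy is the positive
   class). Because the model is linear, the decision decomposes exactly
   over DoFs: the weight–feature product
   $\psi_j = \sum_{m} w_{j,m}\,\phi_{j,m}$ over the four metrics
   satisfies $\sum_j \psi_j + b = w\cdot\phi + b$, and the most negative
   $\psi_j$ names the DoF contributing most to a Compensation call.

## The synthetic study design

No public dataset accompanies this problem, so the package ships a seeded
generator (`generate_dataset()`) emulating the study design the method
targets: 6 participants × 5 tasks (bimanual tray lift; eye-level,
chest-level, pronation and supination reaches) × (1 healthy + 3 acted
compensation conditions) × 5 repetitions = 600 trajectories at 100 Hz,
100 per participant.

Each repetition is a rest-bounded primitive: a minimum-jerk joint-space
ramp ($10s^3-15s^4+6s^5$, the standard rest-to-rest profile of reaching
movements) toward the task's amplitude pattern, followed by a return ramp
to the start pose. Compensation is realized structurally, the way
clinicians describe it: task-primary DoFs are *attenuated* by a factor
$\rho \le 0.7$ (the impairment) and normally quiet torso DoFs are
*recruited* with amplitude $\delta \ge 0.2$ rad (trunk lean, trunk
rotation, lateral lean in the three default conditions). All trajectories
start from the participant's healthy baseline pose, so early frames of
compensatory movements genuinely look healthy.

Around this deterministic skeleton:

* **Torques** come from a decoupled per-DoF surrogate
  $\tau_j = I_j\ddot q_j + b_j\dot q_j + g_j\sin q_j$ with
  participant-specific coefficients — a cheap, invertible stand-in for a
  musculoskeletal inverse-dynamics solve that preserves the
  kinematics-to-torque dependency the features need.
* **Markers** come from a fixed affine forward map $p = Aq + p_0$ with
  moment-arm-scale entries. Linearity makes marker velocity vanish
  exactly when all joint velocities do — the property the segmentation
  assumption rests on — and the sign structure (elbow flexion opposing
  shoulder elevation, as flexion retracts the hand while elevation
  transports it) keeps every task's amplitude pattern well away from the
  map's null space.
* **Noise** is signal-dependent, following the standard motor-control
  observation that movement variability scales with speed: band-limited
  sinusoids (0.3–2 Hz, ~8×10⁻⁴ rad per participant-scaled component)
  modulated by the phase's normalized speed profile over a 0.1 resting
  floor. Band-limited rather than white noise is essential — white noise
  would be annihilated by the 6 Hz low-pass filter and make the jerk and
  effort features degenerate. The resting floor keeps rests quiet enough
  that velocity zero-crossings localize boundaries to a few frames.
* **Seeding is hierarchical** (dataset → participant → trajectory), so
  any subset regenerates bit-identically in isolation, and a healthy and
  a compensatory trajectory built from the same seed differ only by the
  deterministic amplitude changes.

What the generator does *not* emulate: muscle-level dynamics, joint
limits and inter-joint coupling, marker soft-tissue artifact, tremor
above 2 Hz, and the idiosyncratic timing of real acted compensations.
Passing tests on this data therefore demonstrate that the pipeline
recovers structural joint recruitment under realistic smoothness, noise
and inter-participant variability — not that it reaches any particular
accuracy on real motion capture.

## Segmentation

`segment_offline()` follows the classic zero-crossing recipe: smooth the
marker trajectory with a Savitzky–Golay filter (window 0.2 s; order 3, a
package choice that preserves cubic kinematics), differentiate by central
differences, and take frames where all three velocity axes are (near)
zero as primitive boundaries. Two numerical realities are handled
explicitly:

* sampled, noisy velocities never hit exactly zero, so a frame qualifies
  when its largest axis speed is below a tolerance `rest_tol`
  (default 0.02 m/s);
* an entire dwell of frames qualifies around each true rest, so
  qualifying runs within a refractory gap (default 0.15 s) collapse to
  the single frame of minimum speed.

Phases alternate execution/return starting with execution, because every
recording begins at the start pose. Return phases are excluded from
analysis and evaluation throughout — participants follow no protocol
while moving back.

The streaming variant (`online_segmenter()`) keeps a bounded history
(default 5 s) and recomputes rest points every `update_interval` frames
(default 10, i.e. 0.1 s); the current primitive start is the most recent
rest point, and starts never move backwards. A freshly entered rest point
can sit a frame or two off its offline location until the smoothing
window's future context (10 frames) has streamed in; from roughly a
quarter second of age the online and offline starts coincide exactly. The
fixed-length fallback (`mode = "fixed"`, default 1 s) partitions the
stream contiguously for movements that are not rest-bounded.

## Features, normalization, classification

Kinematic and dynamic series are low-pass filtered at 6 Hz before feature
extraction (zero-phase Butterworth, order 4 — the zero-phase pass keeps
kinematics and dynamics synchronized; filter family and order are package
choices). Derivatives everywhere use one central-difference scheme
(`finite_diff()`), so jerk is the derivative of the acceleration series
and effort the second derivative of torque. Aggregation is configurable:
`cae` (default), `windowed` (centered, truncated at boundaries; 0.2 s and
1 s are the standard comparison points) or `none`.

Features are min–max normalized per feature over every frame of the
*training* trajectories only; test values reuse the training min/max and
may fall outside [0, 1] (no clipping). A degenerate feature (training
min = max) maps to 0. In cross-validation the scaler is refitted inside
each fold — normalization is part of the model, and fitting it on pooled
data would leak test information.

Two classifiers are provided behind one fitting function,
`fit_compensation_model()`:

* **LR** minimizes the L2-penalized cross-entropy
  $\sum_i \mathrm{CE}_i + \tfrac{\lambda}{2}\lVert w\rVert^2$
  (intercept unpenalized, $\lambda = 1$ default) with a quasi-Newton
  optimizer (L-BFGS-B), capped at 5000 iterations.
* **SVM** minimizes the squared-hinge soft-margin objective
  $\tfrac12\lVert w\rVert^2 + C\sum_i \max(0, 1-y_i(w\cdot\phi_i+b))^2$
  ($C = 1$ default), same optimizer and cap. The squared hinge is
  differentiable, which is why a smooth quasi-Newton solver applies.

LR confidences are $\sigma(w\cdot\phi+b)$ — the probability the frame is
healthy, with 0.5 meaning maximal uncertainty. The SVM decision value has
no probabilistic scale, so a Platt-style sigmoid is fitted on the
training decision values. Ties ($w\cdot\phi+b = 0$) classify as No
Compensation, matching the decision rule's $\geq$.

Training data replicate each trajectory's single label onto all of its
frames (labels are sparse, one per trajectory), and per-frame predictions
are aggregated back to trajectory level by majority vote; an exact tie
votes Compensation — the cautious call in a screening context.

## Evaluation

Metrics are computed per class and averaged (class-balanced), because the
design yields three compensatory recordings per healthy one: Brier score
(mean squared gap between class indicator and confidence; the per-class
indicator convention is used), miss-classification rate ($1-$recall),
false discovery rate ($1-$precision), and balanced accuracy. Temporal
behaviour is profiled by binning frames into quartiles of elapsed
primitive fraction (right-closed last bin; a bin missing a class is
flagged undefined rather than dropped) — early frames of compensatory
movements start healthy, so accuracy should rise along the primitive.

Cross-validation is leave-one-participant-out: each fold trains scaler
and classifier on five participants and tests on all 100 trajectories of
the sixth. Method comparisons use McNemar's test on paired
per-trajectory votes (continuity-corrected $\chi^2$, with the exact
binomial form available below 25 discordant pairs) with Holm–Bonferroni
correction across each comparison family at $\alpha = 0.05$. Calibration
curves bin confidences into equal-width bins against empirical
frequencies.

## Design decisions worth knowing about

* **Jerk is the third derivative of angle.** The energy-metric family is
  sometimes written with the acceleration symbol, but "angular jerk" as a
  smoothness measure is the third derivative; `compute_raw_metrics()`
  implements that and offers `jerk = "qdd"` as an escape hatch. Likewise
  effort is implemented as printed conventionally ($|\ddot\tau|$) with
  `effort = "tau"` available.
* **Healthy is the positive class.** The decision rule's $\geq 0$ side is
  No Compensation; all probability and metric code documents which class
  a probability refers to.
* **Duplication-stable fits.** The objectives are sum-form with fixed
  regularization, mirroring the common scikit-learn parameterization; on
  overlapping clusters the fitted hyperplane is stable under duplicating
  the dataset to within a few percent, and predictions essentially
  unchanged.
* **Windowed aggregation truncates at boundaries** rather than padding —
  shrinking the window avoids inventing data.
* **The intercept has no per-DoF share**: $\psi_j$ sums weight×feature
  only; $b$ is reported separately by `attribute_joints()`.
* **Attribution is reported at the final frame** of a segment by default
  (where CAE features have integrated the whole primitive), with
  `attribution_trace()` for per-frame traces.

## Problem sizes used in the shipped tests

The test suite exercises the full default design (600 trajectories,
~92,000 execution frames, 6 LOOCV folds, both classifiers) once and
shares the artifacts across assertions; module tests use 2–3 participant
designs with 1–3 repetitions. Streaming tests process single recordings
(a few hundred frames each). `scripts/acceptance.R` re-runs the default
design from scratch — generation, segmentation recovery, LOOCV for both
methods, attribution recovery, and the CAE-versus-none ablation — and
writes every computed quantity to JSON.

## Known limitations

* The generator's compensations are structural (amplitude recruitment),
  not behavioural recordings; classifiers reach ceiling-like separation
  on it. Real acted compensations vary in timing and shape far more.
* The surrogate dynamics are decoupled per DoF; real inter-segment
  coupling makes torque features richer (and noisier).
* Attribution is validated against the generator's injected recruited
  DoFs; no claim is made about anatomical loci in real data, where such
  annotations rarely exist.
* McNemar's test is not applied to streaming outputs: per-frame outputs
  of one trajectory are serially dependent, violating the test's
  independence assumption.
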