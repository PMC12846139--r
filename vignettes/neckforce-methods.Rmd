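---
title: "Methods: personalized cervical muscle-force estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized cervical muscle-force estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`neckforce` implements a complete, self-contained pipeline for
subject-specific cervical biomechanics built on three anthropometric
parameters — head mass (kg), biacromial shoulder width (cm) and neck
length (cm):

1. **Population sampling** — anthropometric profiles drawn from a
   multivariate normal distribution whose mean and covariance ship with
   the package (`ansur_population()`), derived from a large military
   anthropometric survey.
2. **Personalized musculoskeletal simulation** — a parametric
   head–neck linkage is scaled to each profile; standardized neck motions
   are pushed through inverse dynamics and an *enhanced static
   optimization* to produce per-frame muscle forces.
3. **Surrogate learning** — one small feedforward network per muscle
   learns the mapping from nine head-marker coordinates plus the three
   anthropometric parameters to that muscle's force.
4. **Functional assessment** — a subject's observed marker clouds are
   compared against the simulated "ideal" motion envelopes by volumetric
   intersection-over-union (IoU); peak-force ratios between the actual
   and ideal motion localize muscles that are underloaded (possible
   impairment) or overloaded (possible compensation).

This vignette documents the models, the numerical choices, and what the
synthetic data generator does and does not emulate.

# The head–neck model

## Rigid-body reduction

The cervical column is lumped into **two articulations** (skull–C4 and
C4–T1), each a spherical joint decomposed into three revolute DOFs in
the order flexion–extension (about *y*), lateral bending (about *x*),
axial rotation (about *z*).  The torso frame follows the A/L/S
convention: *x* anterior, *y* left, *z* superior, origin at the chain
base (T1).  Sign conventions: positive flexion tilts the head anterior,
positive lateral bending is rightward, positive axial rotation is
leftward.

The two-articulation reduction keeps every quantity the pipeline needs —
a full rigid-body dynamics equation, a redundant muscle space, marker
forward kinematics — while remaining specifiable from the three
anthropometric parameters alone.  Segment masses and inertias default to
scaled cylinders (neck segments) and a sphere (head).  Neck segment
masses are a fixed fraction (8%) of head mass, so total gravitational
demand scales exactly with head mass; the head center of mass sits on
the joint axis at neutral, making the neutral pose moment-free.

Inverse dynamics is a recursive Newton–Euler pass over the six-DOF
chain; it is validated in the test suite against an analytic inverted
pendulum, the Newton limit `tau = I qdd`, and energy conservation of an
integrated passive swing.

## Muscles

The 72 muscles (36 bilateral pairs, names following the standard
cervical-model convention, left partners suffixed `_L`) are straight
lines from torso-fixed origins to insertions on the moving bodies, with
a deep/superficial class per muscle.  The packaged attachment table is a
*documented default geometry*: plausible coordinates on torso landmarks
(sternum, clavicle, acromion, ribs, scapula) and skull/vertebral sites,
bilaterally mirrored, with three deliberate simplifications:

* no via points or wrapping surfaces — muscle paths are chords;
* muscles originating on cervical vertebrae are anchored at the
  corresponding neutral-pose height in the torso frame;
* because the chord-like sternocleidomastoid loses the anterior path it
  has in wrapped models, anterior (deep flexor and hyoid) strengths are
  set toward the upper end of their plausible range so the model meets
  gravitational flexion demand across the full range of motion.  The
  design rule used: one-sided moment capacity at least twice the
  gravitational demand at every range-of-motion extreme.

Moment arms are computed analytically from the chain geometry as the
negative tendon excursion `-dl/dq` and verified against central finite
differences at random poses.

The fast **reduced 16-muscle set** (`muscle_set = "reduced16"`) was
selected by an explicit feasibility criterion — worst-case moment-closure
residual of zero over the standardized motion suite.  Two structural
facts drove the choice: at pure-rotation poses the two articulation
*z*-axes are collinear, so independent lower-joint authority requires a
muscle inserting on the lower neck segment (longissimus cervicis); and at
end-range rotation only muscles with far-lateral origins (omohyoid)
retain an agonist rotation moment arm.

## Passive moments

Each DOF carries a small linear stiffness (0.5 N·m/rad) and damping
(0.01 N·m·s/rad), standing in for ligaments and connective tissue.  They
are configurable and can be zeroed for analytic tests.

# Enhanced static optimization

Per frame the solver distributes the net joint moments `tau` over the
muscles by minimizing

```
sum_i w_i (f_i / f_i^max)^2  +  lambda1 sum_i Phi_i  +  lambda2 sum_i fdot_i^2
```

subject to moment closure `R f = tau`, bounds `0 <= f_i <= f_i^max`, and
(optionally) bilateral symmetry `f_j ~ kappa f_k` between left/right
partners.  Defaults: `w_deep = 0.8`, `w_sup = 1.2`, `lambda1 = 0.01`,
`lambda2 = 0.001`, `kappa = 1.0` with a 0.05 band.

Choices the formulation leaves open, and how this package resolves them:

* **Metabolic form.**  `Phi_i` defaults to the linear normalized-force
  proxy `f_i / f_i^max`, which keeps each frame a strictly convex QP; a
  quadratic alternative is selectable (`metabolic_form`).
* **Force-rate units and discretization.**  The rate `fdot` is
  normalized by `f_i^max` (like the activation term) and discretized
  backward against the previous frame's optimum with the
  time-integral-consistent per-frame weight
  `lambda2 (a_t - a_{t-1})^2 / dt`.  Taken literally in newtons per
  second, the rate term would exceed the activation term by four orders
  of magnitude and make the force distribution history-dominated; the
  normalized form keeps it the small temporal-smoothness regularizer it
  is meant to be.  This matters beyond aesthetics: a history-dominated
  distribution is not identifiable from instantaneous marker positions,
  which is what the surrogate networks consume.
* **Horizon.**  Frames are solved sequentially (receding horizon), each
  using the previous optimum as the rate reference; the first frame has
  no history and solves with the rate term off.
* **Symmetry.**  Soft mode (default) adds a quadratic penalty on
  `a_j - kappa a_k`, scaled so a deviation of the `kappa` band costs
  about one activation unit, and is applied only when the commanded
  motion is sagittally symmetric; hard mode imposes exact equality
  constraints.
* **Numerics.**  The QP is posed in normalized activations with diagonal
  preconditioning (identical optimum, far better conditioning) and
  solved by an established active-set QP routine.  If exact closure is
  infeasible at a pose — the lumped chain is direction-degenerate at a
  few extreme poses — an explicit penalized-closure fallback runs and
  the frame is *accepted only if* its recorded residual meets
  `equality_tolerance` (default 1e-6 N·m); otherwise it is flagged
  infeasible.  Flagged frames are excluded from surrogate training.
  Nothing is silently accepted; per-frame residuals and statuses ship
  with every `force_series`.

# Synthetic motion generation

Standardized tasks (flexion–extension, lateral bending, axial rotation,
combined) are raised-cosine quarter-stroke cycles — neutral, +A, neutral,
−A, neutral — with zero velocity at stroke boundaries, reaching the
commanded amplitude exactly.  Defaults chosen once, a priori: amplitudes
50°/40°/70° (flexion/lateral/rotation), one 8 s cycle per task (the
slow, controlled pace of clinical range-of-motion testing), 100 Hz
sampling.  Commanded head angles split equally between the two
articulations.  "Combined" runs half-amplitude flexion and rotation a
quarter-cycle out of phase; "spontaneous" motions are seeded band-limited
sinusoid sums, amplitude-bounded and windowed to neutral endpoints.

**Restrictions** emulate a movement-impaired subject: excursions into
named direction sectors (e.g. anterior flexion, leftward bending) are
attenuated by a factor in (0, 1], leaving other directions untouched.
Because attenuation scales signed values, trajectories stay continuous
through zero crossings.

Repeated executions can be aligned and averaged with dynamic time
warping (`dtw_average`): symmetric step pattern, Euclidean local cost,
no window, medoid reference (smallest total pairwise DTW distance) — the
variant details are the package's own documented choices.

What the generator does **not** emulate: motor noise and tremor, marker
soft-tissue artifacts and occlusions, inter-trial variability of real
subjects, and intervertebral translation.  Tests passing on these
motions therefore demonstrate the internal consistency of the pipeline
and the learnability of the simulated mapping — not performance on noisy
laboratory recordings.

# Surrogate networks

Each muscle gets an independent network with the fixed architecture
12–64–32–1 (ReLU hidden layers, linear output).  The 12 inputs are the
nine torso-frame marker coordinates (TP, LH, RH × x, y, z) followed by
neck length, shoulder width and head mass.  All features and the force
label are Z-scored with statistics fit on the training split only
(population-SD convention; zero-variance guard replaces sigma by 1 with
a warning).  A configuration switch passes the three anthropometric
features through unstandardized for sensitivity studies.

Splits are two-stage: 20% test held out first, then 20% of the remainder
to validation — 64/16/20 overall.  Splitting is over rows by default
(frames pooled across models); a group-by-profile mode holds out whole
models and is used by the generalization test.

Training hyperparameters (the source formulation leaves them open):
adaptive moment estimation (Adam) at learning rate 1e-3, batch 256, up
to 200 epochs, early stopping on validation loss with patience 20, the
best-validation weights restored; per-muscle seed = global seed + muscle
index, making every ensemble bit-reproducible.  Predictions are
de-standardized and negative raw outputs clipped to zero (forces are
tensile).

Why positions suffice: along single-frequency cycles the acceleration of
each DOF is (nearly) a function of its position, so the inverse-dynamics
torques — and with the convex, history-light solver, the muscle forces —
are recoverable from instantaneous pose plus anthropometry.  On
desk-scale runs (20 profiles × four tasks at 25 Hz, 16,000 rows) the
held-out minimum per-muscle R² is ≈ 0.99 and NRMSE ≤ 0.02; training a
16-muscle ensemble takes well under a minute on one CPU.  Spontaneous
motions break the position–acceleration coupling and are deliberately
not part of the training suite.

# Activation inversion and sEMG processing

Predicted forces invert to activations through the Hill-type relation
`a = F / (F_max · f_l(l) · f_v(v))`, clipped to [0, 1] with a reported
clip count (the inversion can exceed 1 when predicted force outruns the
multipliers).  The multiplier shapes are package defaults — the source
formulation names but does not define them: Gaussian force–length
`exp(-((l_norm - 1)/0.45)^2)` and a Hill hyperbola force–velocity with a
smooth eccentric plateau at 1.4.  For the straight-line muscles,
normalized length is current length over neutral rest length and
normalized velocity its numerical rate.

Surface EMG validation channels run through the standard chain:
Butterworth band-pass 20–450 Hz, full-wave rectification, 10 Hz low-pass,
MVC normalization, resampling to the 100 Hz marker timebase.  Filtering
is zero-phase (forward–backward) so envelopes are not phase-lagged when
correlated against predictions; this doubles the effective order, which
is documented rather than hidden.  MVC normalization follows envelope
extraction.

# Envelopes, IoU and assessment

Per-marker motion envelopes default to the **convex hull** of the marker
cloud (`alpha = Inf`): clouds traced by smooth head motion are
near-convex, and the hull is deterministic and parameter-free.  The hull
is built by an incremental algorithm with exact face-plane volume;
IoU between envelopes is estimated on a common axis-aligned voxel grid
(default 64³ over the joint bounding box) — deterministic and
resolution-controlled, in preference to Monte-Carlo estimates.  A finite
`alpha` is supported as a voxel-grid approximation (hull intersected
with the alpha-dilation of the samples); it is capped by the hull volume
and is not used by any packaged default.  A true 3-D alpha complex would
require a Delaunay triangulation dependency that the package
deliberately avoids.

Assessment: each candidate model's score against a subject is
`IoU_TP + IoU_LH + IoU_RH` (markers equally weighted); the argmax is the
best match, ties broken by lowest model id.  Per-muscle peak-force
ratios (actual / ideal motion) flag possible impairment below 0.85 and
possible compensation above 1.15 — configurable thresholds; the source
analysis states only the direction of the inequalities, the band is this
package's choice.  Ideal peaks below a floor are reported undefined
rather than divided.  The paired t-test on per-marker IoU triplets uses
the standard paired formula (df = n − 1); identical triplets return
t = 0, p = 1 by convention.  Recomputing the t statistic from the
published per-marker IoU table gives t(2) ≈ −6.79, p ≈ 0.021, while the
table prints t(2) = −6.81, p = 0.029 — most likely rounding of the
printed IoUs and/or a different p convention; the package reproduces the
recomputation and records the discrepancy rather than resolving it.

# Problem sizes and reproducibility

Default desk-scale sizes, chosen as the package's own working points:
20 sampled profiles, the 16-muscle reduced model, four standardized
tasks of one 8 s cycle at 25 Hz (16,000 labeled rows) for surrogate
fidelity runs; 10⁶ draws for sampler-recovery checks; 64³ voxels for
IoU.  The full 72-muscle model and 100 Hz sampling are supported
throughout and used in the per-frame physics tests; a million-model
library is supported but never a default.  Every stochastic step
(sampling, splits, initialization, batch order, spontaneous motions)
derives from explicit seeds, and the solver path is deterministic, so
any artifact regenerates bit-identically from its config and seed on one
platform.

# Known limitations

* The two-articulation chain cannot localize deficits to individual
  intervertebral levels, and straight-line muscles misstate moment arms
  at extreme poses compared with wrapped-path models.
* Muscle attachment coordinates and maximal forces are plausible
  defaults, not subject-measured values; absolute force magnitudes
  should be read comparatively, not clinically.
* The surrogate's accuracy statement is conditional on motions close to
  the standardized suite; free-form motion breaks the
  position–acceleration coupling that makes instantaneous features
  sufficient.
* sEMG comparison is pattern-level by design: amplitude agreement is not
  claimed, and crosstalk is not modeled.
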