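---
title: "comgait: models, signal processing and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{comgait: models, signal processing and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`comgait` implements a complete pipeline for predicting lower-limb kinetics
and kinematics during walking from a single sacrum-mounted accelerometer: a
mechanical model of the walking center of mass (CoM) that motivates the
sacrum as the one place worth instrumenting, a synthetic data generator that
stands in for a human cohort, the IMU preprocessing chain, planar inverse
dynamics for ground-truth joint torques, and a small feed-forward network
evaluated leave-one-subject-out (LOO).  This vignette explains the science in
each stage, the tunable parameters and their defaults, and the design
decisions taken where the design was genuinely open.  It states no empirical
result that the package's tests and `scripts/acceptance.R` do not themselves
compute.

## 1. The compliant walking model

The stance model is a spring-loaded inverted pendulum (SLIP) extended with an
off-centered rolling ("curvy") foot: a point mass `m` rides on a massless
leg whose axial spring (stiffness `k`, rest length `l0`, measured contact to
CoM) ends at an ankle placed a distance `d` behind the center of a foot arc
of radius `R` that rolls on the ground.  The foot is locked to the leg
orientation by a constraint torque, so stance has two degrees of freedom:
the CoM-ankle length `ls = l - R` and the leg angle `theta`
(clockwise-positive from vertical; negative at touchdown when the contact is
ahead of the CoM).

Because the leg-foot assembly is massless, it is in equilibrium at every
instant.  The spring force `F = k (l0 - l)` acts along the leg, the
prismatic constraint transmits a perpendicular force
`fa = -F (d + R sin(theta)) / (ls + R cos(theta))` (from the torque balance
about the rolling contact), and the resulting ground reaction force (GRF)
passes through the CoM.  Its moment about the ankle is the extension-positive
ankle torque `Ta`.  One can verify directly that the constraint forces are
workless, so the stance dynamics conserve kinetic + gravitational + elastic
energy; `simulate_stance()` integrates them with fixed-step 4th-order
Runge-Kutta (default `dt = 1e-4` s) and locates liftoff (the axial force
crossing zero after loading) by bisection to `dt/100`.  The energy drift and
its 4th-order convergence are asserted by the test suite, as is the
point-foot limit `R = d = 0` against an independent integrator and the
time-reversal symmetry of stances passing through a mirror-symmetric
midpoint.

### Default parameters

| parameter | default | rationale |
|---|---|---|
| `m`, `h` | 72 kg, 1.69 m | cohort means of the reference study population |
| `l0` | `0.9 h / 1.8` = 0.845 m | leg spring spans contact to CoM |
| `k` | `20 m g / l0` | dimensionless leg stiffness `k l0/(m g) = 20`, literature-typical for compliant walking |
| `R` | 0.3 m | rolling foot radius, typical for curvy-foot walking models |
| `d` | 0.05 m | ankle offset; produces the forward center of pressure and a human-like extension torque |
| `l1`, `l2` | `0.52 (l0 - R)` each | thigh/shank split the rest CoM-ankle length with 4% slack, keeping the knee bent away from the straight-leg singularity |
| `l3` | `0.152 h` | foot segment length (anthropometric tables), used by inverse dynamics |
| `k_a` | 500 N m/rad | retained for interface compatibility; the dynamics lock the foot to the leg with a constraint torque, so `k_a` is inert |

### The affine CoM maps and the coefficients `cl`, `ck`

Linearized about the reference configuration (vertical leg, uncompressed
spring), the CoM position determines the augmented state
`z = (l, theta, l*theta)` through an affine map whose only ingredients are
the touchdown height `y_hs` and the frozen offset
`alpha = R theta_hs - c_hs + d`.  The inclusion of the product `l*theta` in
`z` is what lets maps quadratic in `(l, theta)` stay *affine* in `z`: the
GRF/ankle-torque map `f = W2 z + b2` is then the exact expansion of the
nonlinear force law through second order, which the test suite verifies by a
log-log error-slope test (slope 2 over perturbations `1e-4 ... 1e-1` m).

Two scalar coefficients appear in those matrices:

* `cl = 1 - R/l0` - the factor by which the rolling-foot geometry scales the
  ankle moment of the GRF; with it, the ankle-torque row
  `Ta = cl * k (l0 - l) (d + R theta)` is the exact linearization of the
  constraint torque.
* `ck = 1 - l1 * gamma1`, where `gamma1` is the sensitivity of the thigh
  angle to the leg length in the exact two-link inverse kinematics at the
  reference.  The segment-angle rows also carry the constant knee-bend
  offsets `beta1_0`, `beta2_0` of the bent reference chain.

Both are computed at construction time from the package's own nonlinear
models and exposed as `slip_params()` fields so tests can pin them.  The
swing-leg rows are the mirror image of the stance rows (steady symmetric
gait): only the length-dependent column and the bias flip sign, which is
asserted structurally.

Note one deliberate limitation: the state map drops the `O(d*theta)` term in
the CoM height, so exact first-order agreement between the stacked affine
map and the simulator holds at a vanishing ankle offset; the
linearization-consistency tests therefore use `d ~ 0` (with extra knee slack
for the inverse-kinematics oracle's reach).  At the default `d = 0.05` m the
agreement degrades at first order by about `d/l0` (~6%), which is the price
of the height approximation, not an implementation defect.

## 2. The synthetic cohort: what it emulates, and what it does not

The human dataset behind the reference numbers is not deposited, so the
package generates its own world with `generate_walking_trial()` /
`generate_cohort()`.  Consecutive stances of the nonlinear model are
stitched with *finite double support*: a new leg (uncompressed, at a
touchdown angle drawn per step) becomes active when the CoM descends through
its touchdown height while the old leg is still loaded, and the old leg is
dropped when its spring unloads.  Zero double support is not an option: the
event-truth ordering (apex < HS < TO within a cycle) and the toe-off
signature (the contralateral braking trough) both require it.

Three non-conservative ingredients make the gait robust and human-like:

* **Leg damping** (`damping = 700` N s/m, in parallel with the spring):
  absorbs the touchdown transient the way muscle and soft tissue do.  A
  purely conservative stitched gait bounces (running-like) and loses forward
  speed catastrophically; with damping the model walks at all cohort speeds
  with vertical CoM excursions of roughly 1-7 cm and double support shrinking
  from ~130 ms at 1.0 m/s to ~10 ms at 2.3 m/s, the correct trends.
* **A per-step speed regulator** (proportional-integral velocity nudge at
  each touchdown, gain 0.5 / integral 0.4): emulates steady treadmill
  walking; at steady state the mean speed tracks the requested speed to
  better than 0.5% and the per-step corrections are small.
* **Touchdown-angle adaptation**: the policy angle is
  `-0.32 - 0.03 (v - 1)` rad with 0.01 rad step-to-step jitter; a subject
  whose jittered mechanics cannot walk there steepens it (instability) or
  shallows it (flight - the protocol demands walking, with double support).

The sacrum signal is the CoM acceleration plus a heel-strike impact
transient - a damped 30 Hz ringing, positive first (the impact arrests the
falling mass, then rebounds), written as the exact derivative of a decaying
oscillation so it carries **zero net impulse** (ringing must not change the
integrated velocity).  Both channels then pass a *causal* second-order
anti-alias filter (the sensor front end; causal so the transient rings only
after contact) before decimation to 100 Hz.  Sensor corruption
(`corrupt_to_imu()`) adds white noise (0.15 m/s^2), a constant bias
(0.05 m/s^2) and a linear bias ramp (0.01 m/s^3) - values chosen once for a
consumer MEMS part worn over clothing; the reference device's quantization
floor (0.001 g) is far below them.

Ground-truth labels are computed per stance: GRFs and the center of pressure
from the leg force law at 200 Hz aligned to the 100 Hz clock, stance-leg
segment angles by exact two-link inverse kinematics, swing-leg angles from
the contralateral stitched step (true geometry during its stances, Hermite
ankle interpolation with toe clearance across its swing), and joint torques
by the planar Newton-Euler recursion of section 4 - computed on a slightly
extended window and trimmed, so the double differentiation never sees a
one-sided edge.  Cohort anthropometry is standardized to the reported sample
statistics (1.69 +/- 0.075 m, 72 +/- 7.7 kg *realized*, not just in
expectation), with +/-10% multiplicative jitter on `l0` and `k`; per-subject
treadmill speeds default to the reference table
(`cohort_speeds()`).

What a green test does **not** establish: the generator has no soft-tissue
artifact, no gyroscopic/3D content, no inter-stride long-range variability
beyond the touchdown jitter, and its hip torque is purely inertial (the
point-mass model has no hip actuation).  Passing the synthetic analogs does
not certify performance on human data; it certifies that the pipeline's
machinery is correct on a world whose every quantity is known.

## 3. Preprocessing

Event detection follows the cascaded rule set on two low-passed copies of
the vertical channel (10 Hz for the apex, 40 Hz for heel strike) and one of
the horizontal channel (10 Hz for toe off), with zero-phase (forward +
backward) 5th-order Butterworth filters - zero-phase because event timing
must not be phase-shifted.  Deviations from a naive reading, and why:

* the apex search accepts only *negative* minima of the 10 Hz vertical trace
  (at a height maximum the vertical acceleration is necessarily negative),
  which rejects the shallow positive minima around liftoff;
* the refractory spacing between admissible extrema is capped per trace at
  the half-period of that trace's cutoff (a blanket 50 ms would erase the
  40 Hz structure around heel strike);
* extrema must stand out by a windowed prominence of 0.25 m/s^2 on both
  sides; noise-free synthetic signals expose micro-features (e.g. the small
  damper-induced dip before touchdown) that a strict neighbour comparison
  would accept, while real signals hide them under noise;
* the "positive local maximum" preceding the HS trough is implemented as the
  first prominent local maximum - in kinematic units (gravity removed) the
  push-off crest can sit below zero.

The HS-before-TO validation keeps the published re-identification rule.
Note the cycle anatomy: a detected cycle's HS is the touchdown of the *next*
leg and its TO is the liftoff of the leg whose apex opened the cycle, so one
stance runs from the HS of one cycle to the first TO at least `min_stance`
(0.2 s) later - this pairing is what `segment_trial()` implements.

Integration: velocities come from cumulative trapezoids with the linear
drift ramp removed.  The ramp is applied over the *apex-to-apex window
bracketing the stance*, where steady-gait periodicity (and hence the
zero-mean vertical-velocity assumption) actually holds, and the stance is
sliced afterwards; over a bare stance window the assumption fails because
the model lifts off 2-3 cm higher than it touches down (the ankle offset
`d`).  The horizontal velocity gets the regression speed offset
`v0 = (a A + b f + c) sqrt(h g)` - least squares on the training subjects
only - where `A` is the mean acceleration magnitude and `f` the stride
frequency (inverse time between ipsilateral heel strikes); the printed form
of the normalization is read as `sqrt(h g)` for dimensional consistency.
The vertical offset is zero (steady walking).  Positions integrate the
compensated velocities, with the horizontal position reset to zero at heel
strike and the vertical offset set to the subject's leg length.  Each stance
is then resampled to 200 points of normalized phase; the time feature is
the phase fraction (0 to 1), a deliberate resolution of an ambiguity - an
absolute-seconds channel would carry arbitrary trial-clock information.

Feature normalization ("0 to 1") is per-channel min-max with extrema frozen
on the training fold of each LOO split - the second reading of an ambiguous
phrase (division by the maximum norm) differs only by an affine
reparametrization that the network absorbs.

## 4. Inverse dynamics

`planar_inverse_dynamics()` is a bottom-up Newton-Euler recursion
foot -> shank -> thigh in the sagittal plane.  Segment inertial properties
come from the standard anthropometric fractions (Winter's tables:
mass 1.45/4.65/10.0% of body mass; CoM at 50/43.3/43.3% from proximal;
radius of gyration 47.5/30.2/32.3% of segment length), config-overridable;
the exact table behind the reference study is not reproduced there, so these
standard values are a flagged substitution.  Kinematic derivatives are
central differences after a 10 Hz low-pass (matching the motion-capture
processing being emulated); the CoP on synthetic data is the rolling-foot
contact point.  Torques are reported clockwise-positive, which at the ankle
is extension (plantarflexion) positive: a vertical GRF acting a distance
delta anterior to the ankle produces `T_ank = fy * delta` in static stance.
The recursion is validated against the closed-form pendulum torque to
machine precision when analytic accelerations are supplied.

## 5. The predictor and its evaluation

The network maps each of the 200 phase samples of a stance independently
(7 inputs -> 20 sigmoid hidden units -> 11 linear outputs), which is the
form suggested by the affine CoM-to-outputs approximation: a weighted sum of
the CoM kinematics through one mild nonlinearity.  Training is mini-batch
Adam on the mean squared error over all 11 channels, with labels normalized
per channel so forces (hundreds of N) do not drown angles (radians).
Hyperparameters are not stated by the source study; the package defaults are
learning rate 3e-3, batch 1024 columns, up to 300 epochs with early stopping
on a 10% validation split (patience 50), all exposed in `train_config()`.
The batch/learning-rate defaults are larger than typical small-network
folklore purely for single-CPU runtime; the acceptance harness uses 150
epochs at rate 1e-2 for the same reason and says so.

Two subject-scale choices matter for leave-one-subject-out generalization:

* **Size-normalized labels.**  Kinematics cannot carry body mass, so a
  network trained on absolute forces misjudges the scale for a mass-extreme
  held-out subject (near-unity correlation, large offset).  The harness
  therefore trains on dimensionless labels - forces per body weight `m g`,
  torques per `m g h` - and rescales predictions with the *test subject's
  known anthropometry*.  This extends the study's own size-normalization
  rationale (the speed offset is normalized by `sqrt(h g)`; the position
  offset is the subject's leg length) and uses only measured covariates, not
  test labels.
* **No leakage.**  Per fold, the speed-offset regression, both normalization
  extrema and the network are fitted on the remaining subjects only; an
  assertion inside `loo_evaluate()` audits that no held-out segment enters
  training.

Metrics are reported per channel x subject x speed: NRMSE in percent
(normalizer = the observed range of that subject's channel at that speed),
MAE in channel units, and Pearson correlation.  The harness supports
speed-restricted training sets (e.g. moderate only) and input ablations
(e.g. dropping the displacement rows), mirroring the study's sensitivity
analyses.

## 6. Numerical choices and degenerate inputs

* Butterworth filters are designed by bilinear transform (all zeros at
  `z = -1`, exact unit DC gain); zero-phase filtering uses odd-reflection
  padding and steady-state initial conditions, so constants pass through to
  round-off and a sinusoid at the cutoff is attenuated to exactly half power
  after the double pass.
* The walking generator integrates at `dt = 1e-3` s (recording at 200 Hz);
  `simulate_stance()` defaults to `1e-4` s.  Energy-conservation convergence
  is measured at `4e-3 -> 2e-3` s, where truncation still dominates
  round-off (the drift at `2e-3` is already ~1e-10 of the total energy).
* Ties among extrema break to the earliest index; stance segmentation
  rejects windows shorter than 0.2 s or longer than 1.4 s.
* Degenerate normalization channels (max = min) map to 0.5 with a warning;
  a rank-deficient speed-offset design (constant `A` and `f`) is an error;
  an unreachable inverse-kinematics target or a contact-inconsistent initial
  state is an error naming the quantity.
* All randomness is seeded: trials are byte-identical given a seed; two
  trainings with one seed produce identical weights.

## 7. Known limitations

Sagittal plane only; massless legs (hip torque is inertial bookkeeping, and
its prediction is correspondingly the weakest channel, as in the reference
study); no gyroscope or 3D channels; the walking generator is an actuated,
regulated gait rather than a passive limit cycle, and its touchdown-angle
policy is a modeling convenience, not an inference about human control; the
synthetic cohort's difficulty is not calibrated to match human inter-subject
variability, so the pipeline's synthetic LOO errors are smaller than the
reference study's human ones.
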