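---
title: "Whole-body inverse dynamics from inertial motion capture: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body inverse dynamics from inertial motion capture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbid)
```

## The problem

Inverse dynamics estimates the net forces and moments that must have acted
at the joints, given the observed motion and the inertial properties of the
body segments. The classical laboratory setup needs optical motion capture
and floor-mounted force plates; `wbid` implements the alternative: a
whole-body inverse-dynamics model driven by an inertial motion-capture
(IMC) suit alone. The ground reaction forces (GRFs), normally measured by
the plates, are themselves estimated from the kinematics, which makes the
analysis portable — field ergonomics, worksite lifting assessments,
outdoor gait — at the price of the modelling assumptions documented here.

## Body model

The body is a rigid multibody system of 15 segments (pelvis, torso, head,
and left/right upper arms, forearms, hands, thighs, shanks, feet) joined by
14 joints (neck, L5/S1, shoulders, elbows, wrists, hips, knees, ankles) in
a tree rooted at the pelvis. Segment masses, lengths, centre-of-mass
offsets and inertia tensors are scaled from the subject's stature and body
mass with sex-specific regression coefficients
(`inst/extdata/bsip_coefficients.csv`, after the adjusted
regression tables of Dumas and colleagues, with segment lengths from the
classical Drillis–Contini stature proportions). Two deliberate
simplifications: transverse CoM offsets are neglected (the offset runs
along the segment's long axis only) and the inertia tensor is diagonal in
the segment frame (principal-axis radii of gyration, no products of
inertia). Head and neck are merged into a single segment. Raw mass
fractions do not sum to one, so they are renormalised to the measured body
mass — the whole-body force balance below relies on exact mass
conservation.

All computation uses a right-handed, Z-up, X-anterior frame; BVH files
(Y-up, centimetres by default) are converted once at ingest, so a single
axis convention holds everywhere downstream.

## From sensors to segment states

Each segment carries an orientation (from the motion stream) and, where an
IMU is present, a measured linear acceleration `a_si` and angular velocity
`omega_i` in the global frame. The segment CoM acceleration is
reconstructed with the rigid-body lever-arm relation

    a_i = a_si - alpha_i x r_si - omega_i x (omega_i x r_si)

where `r_si` locates the IMU relative to the CoM. Angular acceleration
`alpha_i` is obtained by numerically differentiating `omega_i` (central
differences in the interior, second-order one-sided stencils at the ends —
the derivative is exact for quadratics everywhere, so the scheme is
second-order accurate including the endpoints). The default IMU placement
table puts each sensor at the segment CoM (`r_si = 0`); real placements can
be supplied per segment, and the lever-arm correction is covered by unit
tests with non-zero offsets.

Accelerometer streams are treated as gravity-free in the internal
contract. A single flag (`gravity_included`) strips +g at ingest for
streams that contain it, so gravity can never be double-counted against
the explicit weight terms in the force balance.

Measured channels pass through a second-order zero-phase (forward–backward)
Butterworth low-pass filter, default cutoff 10 Hz, before any
differentiation. The filter pads by odd reflection so that constants pass
through unchanged and edge transients stay outside the returned window.
For noiseless synthetic input the filter is disabled (`filter_cutoff =
NULL`): it exists to suppress measurement noise, and even its tiny
passband ripple is visible against the sub-millinewton numerical error of
a noise-free round trip.

## Total ground reaction

With no other environmental contacts, the whole-body Newton and Euler
balances give the total reaction the ground must supply:

    F_g = sum_i (m_i a_i - W_i - F_ex,i)
    M_g = sum_i (M_i* + l_i x (m_i a_i) - l_i x W_i - M_ex,i - l_ex,i x F_ex,i)

with `W_i = (0, 0, -m_i g)`, `M_i* = I_i alpha_i + omega_i x (I_i
omega_i)` in the global frame, and all positions `l` taken relative to the
pelvic-frame origin. External loads (`F_ex`, e.g. a hand-held box) are
active forces prescribed by the task schedule. `F_g` is the reaction the
ground applies, vertical positive up; `g = 9.81` m/s².

## Foot contact detection

Contact is decided per foot by a velocity-threshold state machine. The
foot enters stance when the toe speed drops below a threshold `v_th` and
leaves it when the toe speed reaches the threshold again. A second
stance-termination rule separates toe-off from a slow leg lift: stance
also ends when the heel's tangential acceleration (the derivative of heel
speed) switches sign from positive to negative — the heel passing its
speed maximum — while the toe stays slow. The default `v_th` is fixed at
1.2 m/s, the average walking speed of a healthy adult; an alternative
mode sets it to the trial's mean forward pelvis speed (both conventions
are in circulation; the fixed value is the package default, the pelvis
mode a configuration switch).

One guard is this package's own: the heel rule only fires when the heel is
actually moving faster than `v_th / 2`. Without the gate, every local
maximum of the never-quite-zero heel speed of a loaded stance foot (or the
numerical jitter of a resting one) would terminate stance. The gate value
is half the contact threshold so it scales with `v_th`.

Note a consequence of the literal machine: re-entry into stance requires
only a slow toe, so a heel-rule event whose toe never speeds up produces a
momentary swing. Sustained swing needs the toe to cross `v_th`, which is
what happens in gait and in brisk leg lifts.

## Double-stance decomposition

During single stance the stance foot receives the full `(F_g, M_g)`; with
no contact the totals are reported as a flight-phase residual rather than
forced onto the feet. Double stance is statically indeterminate, and the
split is chosen by minimising muscular effort as proxied by the net
lower-limb joint moments:

    min ||M_ra||^2 + ||M_la||^2 + ||M_rk||^2 + ||M_lk||^2 + ||M_rh||^2 + ||M_lh||^2

over the right-foot wrench `(F_rg, M_rg)`, subject to the equality
constraints `F_rg + F_lg = F_g`, `M_rg + M_lg = M_g` (used to eliminate
the left wrench) and to non-negative vertical force on each foot. Each of
the six ankle/knee/hip moments is an affine function of the unknowns —
they are bottom-up Newton–Euler wrenches of the stance chains — so the
problem is a convex quadratic program in six variables with two inequality
constraints on one coordinate. A dedicated active-set step solves it
exactly per frame: solve the unconstrained normal equations; if the
vertical split violates a bound, re-solve with that bound active and keep
the better feasible candidate. A ridge of 1e-12 returns the minimum-norm
solution when the objective is degenerate (e.g. massless-limb toy
models). The inequality is implemented as a closed constraint (≥ 0) for
well-posedness.

Choices the method itself leaves open, resolved here:

* **Application point.** The per-foot reaction is applied at the vertical
  projection of the ankle centre onto the ground plane (configurable to
  the foot-CoM projection). A genuine centre of pressure is not estimable
  without pressure sensing.
* **Frame of the objective.** Moments enter the objective in the global
  frame; the squared norm is invariant under per-joint rotations, so the
  choice is benign (asserted in the tests).
* **Per-frame independence.** The QP is solved frame by frame with no
  temporal smoothness term, matching the per-frame definition of the
  optimisation.

## Joint loads, dynamic and static

The Newton–Euler recursion runs in two directions: top-down over the upper
body (hands → forearms → upper arms, head → torso, ending at L5/S1),
starting from the known weight of hand-held objects, and bottom-up over
the lower body (feet → shanks → thighs), starting from the estimated
per-foot reactions. Each segment's balance is solved about its CoM in the
global frame and the resulting wrench is reported about the joint centre;
the two chains together yield all 14 joints. The pelvis closes the loop:
its residual balance (given L5/S1 and both hips) is a whole-body
consistency diagnostic that vanishes when the reactions are exact.

The *static* flavour repeats the identical recursion with every segment's
linear acceleration, angular velocity and angular acceleration set to
zero, and with the ground reactions recomputed under the same zeroing —
a posture-only model in the tradition of static strength-prediction
software. Angular velocity is zeroed along with the accelerations because
such tools are strictly posture-driven; centripetal terms are motion, not
posture. The `peak_ratio` of dynamic to static peak moment magnitude
quantifies how much a posture-only analysis underestimates loading.
Hand-held loads default to a 50/50 split between the hands during
two-handed carries, configurable per task.

## Synthetic trials and what they do (not) show

Because no reference recordings ship with the package, a first-class
generator produces trials with exact ground truth. Motions are prescribed
in closed form (harmonics, gaussian bumps, gaussian-windowed bursts, all
with analytic first and second derivatives) and propagated exactly down
the kinematic chain — rotations, angular velocities and accelerations,
point velocities and accelerations. The truth therefore satisfies
Newton–Euler identically, with no numerical differentiation anywhere in
its construction. Each trial also renders the artefacts the pipeline
ingests (a BVH motion file, a sensor CSV), so round trips exercise
parsing, unit conversion and Euler-angle handling end to end.

Four templates emulate the tasks of interest: quiet standing with optional
postural sway; a gait-like template (antiphase hip harmonics tuned to be
rolling-consistent with the forward speed, knee flexion peaking mid-swing,
counter-swinging arms) that produces alternating single stance with about
13% double stance and clean threshold crossings; a weight-shift/leg-lift
trial; and a stoop lift with a 17 kg box active between grasp and release,
mid-lift effort wiggles, and an optional deposit-impact transient that
spikes the dynamic (but not static) shoulder and low-back moments.

Two constructions deserve honesty:

* During double stance the truth split is defined by the same
  minimum-moment criterion the estimator uses (evaluated on the analytic
  states). Round-trip agreement therefore validates the numerical
  fidelity of the discrete pipeline — file I/O, filtering,
  differentiation, the lever-arm reconstruction — not the split criterion
  itself. The criterion is checked independently against a brute-force
  grid oracle and closed-form symmetric cases.
* The truth contact timeline applies the package's own state machine to
  the analytic marker velocities. Detector and truth share the rule; what
  the round trip shows is that numerically differentiated velocities
  reproduce the analytic transitions to within a frame.

The generator does not emulate soft-tissue artifact, sensor-fusion drift,
magnetometer disturbance, foot–ground contact mechanics (feet may hover
during template gait), or friction. Passing round trips bound the
pipeline's numerical error; they say nothing about those physical error
sources in real recordings.

Default conditions: 120 Hz sampling; a 1.77 m, 78.9 kg male reference
subject; accelerometer/gyro noise, when requested, is white gaussian with
configurable SD behind a single integer seed. Trial lengths used in the
shipped tests are 2–4 s of standing, two 1.4 s strides of gait, and a
6.5 s lift — sizes chosen so the full suite and the acceptance script
re-run comfortably on a laptop-class single core.

## Agreement metrics

`rmse` is the discrete root-mean-square difference; `rrmse` normalises by
the peak absolute value of the *reference* series (so it is deliberately
asymmetric) and reports percent. Peak agreement uses the two-way
random-effects, absolute-agreement, single-measure intraclass correlation
ICC(2,1) — the framework's form is not uniquely determined by convention
in the application literature, so the choice is logged in every report.
Categories are poor (≤ 0.5), moderate (≤ 0.75), good (≤ 0.9), excellent
(> 0.9); as printed the boundaries overlap, and this package resolves
ties downward ("excellent" strictly above 0.9, consistent with an ICC of
exactly 0.90 being reported as good agreement).

## Numerical choices, degenerate inputs, limitations

* Filtering precedes differentiation; both are linear, and they commute on
  band-limited signals away from the edges (property-tested).
* The QP active set has at most one active bound (both bounds coincide
  only when the total vertical force is zero); infeasibility can only
  arise from a negative total vertical reaction during labelled double
  stance, which is guarded with an error naming the frame.
* Flight-phase residuals above 5% of body weight trigger a warning in the
  run log — an honest accounting for jump-like trials rather than forcing
  the residual onto airborne feet.
* Missing sensor channels fall back to motion-derived kinematics (logged);
  missing-data gaps up to 0.1 s are linearly interpolated, longer gaps are
  a data-quality error.
* Anterior–posterior and mediolateral GRF components are intrinsically
  harder than the vertical one: they carry no weight term and are driven
  entirely by inertial (and, in reality, friction) forces. Expect the
  vertical component to dominate any real-data agreement, as the
  validation literature consistently reports.
* Joint loads are *net* (resultant) loads: no muscle-force partitioning,
  no joint contact forces, no lumbar compression/shear decomposition.

## Reproducing the shipped numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every
headline quantity from scratch: statics closure on a quiet stand,
forward–inverse round-trip errors on gait and lift, the QP-versus-grid
optimality gap, contact-transition recovery, dynamic/static peak ratios
on the impact lift, noise robustness of the vertical GRF, and the metric
self-checks. The testthat suite covers the same ground plus the
per-module contracts.
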