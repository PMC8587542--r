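# wbid — whole-body inverse dynamics from inertial motion capture

`wbid` estimates the loads acting inside the human body — total and
per-foot ground reaction forces/moments (GRF/GRM) and the net forces and
moments at 14 major joints — from the kinematics recorded by an inertial
motion-capture (IMC) suit alone, with no force plates. It is aimed at
biomechanics and ergonomics work outside the laboratory: lifting
assessments, gait analysis, low-back (L5/S1) and shoulder loading in the
field.

## The method in brief

The body is a 15-segment rigid multibody model (regression-scaled masses,
CoM offsets and inertia tensors from the subject's height, mass and sex).
Per frame:

1. **Segment states.** Segment CoM acceleration is reconstructed from the
   segment-fixed IMU via
   `a_i = a_si − α_i × r_si − ω_i × (ω_i × r_si)`;
   angular acceleration comes from differentiating the gyro signal.
   Channels are low-pass filtered (zero-phase 2nd-order Butterworth,
   10 Hz) before differentiation.
2. **Total ground reaction.** Whole-body balance:
   `F_g = Σ_i (m_i a_i − W_i − F_ex,i)` and
   `M_g = Σ_i (M_i* + l_i × m_i a_i − l_i × W_i − M_ex,i − l_ex,i × F_ex,i)`
   with `M_i* = I_i α_i + ω_i × (I_i ω_i)`, moments about the pelvic
   origin.
3. **Foot contact.** A per-foot state machine on the toe speed against a
   threshold `v_th` (default 1.2 m/s), with a heel-acceleration rule that
   ends stance when the heel passes its speed maximum (toe-off vs leg-lift
   disambiguation).
4. **Double-stance decomposition.** The statically indeterminate split of
   `(F_g, M_g)` between the feet is resolved by a convex quadratic
   program minimising
   `‖M_ra‖² + ‖M_la‖² + ‖M_rk‖² + ‖M_lk‖² + ‖M_rh‖² + ‖M_lh‖²`
   (net ankle/knee/hip moments of the stance chains) subject to
   `F_rg + F_lg = F_g`, `M_rg + M_lg = M_g` and non-negative vertical
   force per foot.
5. **Joint loads.** A recursive Newton–Euler sweep, top-down for the upper
   body (from hand-held loads to L5/S1) and bottom-up for the lower body
   (from the per-foot reactions to the hips), in dynamic form or in a
   *static* (acceleration-free, posture-only) flavour.

Agreement metrics (RMSE, relative RMSE in % of the reference peak,
ICC(2,1) with poor/moderate/good/excellent categories) and a synthetic
trial generator with exact ground truth round out the package. The
methods vignette (`vignettes/whole-body-inverse-dynamics.Rmd`) documents
the model, assumptions, parameters and design decisions.

## Worked example

Simulate a stoop lift of a 17 kg box (with the deposit-impact transient),
write it as an on-disk fixture (BVH + sensor CSV + manifest), and run the
full pipeline in both flavours:

```r
library(wbid)

subject <- subject_record(height = 1.77, mass = 78.9, sex = "male")
trial <- generate_lift(subject, box_mass = 17, impact_transient = TRUE)

dir <- tempfile("lift_fixture")
write_trial_fixture(trial, dir)

fx <- read_trial_fixture(dir)
run <- run_pipeline(fx$motion, fx$sensors, fx$subject, loads = fx$loads,
                    v_th = fx$v_th, flavor = "both")
print(run)
#> <wbid_run> 780 frames @ 120 Hz, flavor=both
#>   peak total vertical GRF: 1086.2 N; double-stance frames: 780

pr <- run$peak_ratios
pr[pr$joint %in% c("l5s1", "shoulder_r", "shoulder_l"), ]
#>       joint    ratio
#>        l5s1 6.839717
#>  shoulder_r 1.484266
#>  shoulder_l 1.484266
```

The peak vertical GRF (1086 N) exceeds body weight plus box weight during
the lift because the upward acceleration of the trunk adds inertial load;
both feet stay in stance throughout, so every frame is decomposed by the
QP. The peak ratios say that a posture-only (static) analysis would
underestimate the peak L5/S1 moment roughly 7-fold on this trial (the
deposit impact dominates) and the shoulder moments by about 48%.

Validating the estimated reactions against force-plate style records —
here the trial's own ground truth re-exported as plate files — reproduces
the standard component-wise agreement table:

```r
val <- validate_reactions(run$reactions, truth_forceplate(trial),
                          frame_rate = 120, align = FALSE)
val$table[val$table$signal == "total", ]
#>  signal component     rmse    rrmse
#>   total        VE 3.57e-13 3.29e-14
#>   total        AP 9.03e-13 1.96e-13
#>   total        ML 0.00e+00       NA
```

(`VE`/`AP`/`ML` = vertical, anterior–posterior, mediolateral; rRMSE in
percent of the reference peak; `NA` where the reference component is
identically zero.)

A thin command-line wrapper is installed as `exec/wbid`:

```sh
wbid simulate --kind gait --height 1.77 --mass 78.9 --sex male --out fx --seed 1
wbid run --fixture fx --out results --flavor both
wbid validate --fixture fx --plates plates.txt --out report.json
wbid metrics --reference ref.csv --candidate cand.csv --column total_fz
```

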