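---
title: "Estimating and predicting passive shoulder torque from robot-guided abduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and predicting passive shoulder torque from robot-guided abduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passivetorque)
```

## The measurement model

A relaxed upper limb is strapped into an orthosis bolted to the flange of
a 7-DoF collaborative arm and dragged through slow abduction trajectories.
Under four assumptions the recorded robot data determine the shoulder's
passive torque at every sample:

* **Rigid body** — limb plus orthosis move as one rigid body fixed to the
  flange, so the flange-to-shoulder transform is a constant, determined
  once at a reference pose (`calibrate()`).
* **Ball-and-socket shoulder** — rotation about a fixed centre. The centre
  is estimated by least-squares sphere fitting of the elbow landmark's
  path; posture is then two globographic angles (plane of elevation,
  elevation), which exclude axial rotation of the upper arm.
* **Quasi-static motion** — at rehabilitation speeds inertial and viscous
  contributions are negligible, so force and moment balance hold at each
  instant. Samples whose flange speed exceeds 0.1 m/s (configurable) are
  flagged.
* **Passive muscles** — all measured resistance is gravity plus soft
  tissue; the package has no way to verify this and treats it as part of
  the protocol.

The chain per sample is: smooth the external joint torques, recover the
flange wrench from `tau_e = J' f` by SVD pseudo-inverse, subtract the
orthosis weight, and transport the wrench moment to the shoulder centre:
`M_P = -M_R - M_FR`. The resulting `(plane, elevation) -> M_P` samples
train a 2-H-3 sigmoid network by Levenberg-Marquardt, which then predicts
the torque field at unmeasured postures.

## Conventions that the data do not fix

Several datums are conventions rather than measurements; they are fixed
here once and stated explicitly because downstream numbers depend on them.

* **World frame**: right-handed, Z vertical up; the subject sits with the
  coronal axis along world X and the sagittal axis along world Y.
* **Globographic datum**: elevation is measured from the downward vertical
  (arm hanging = 0), plane of elevation from world X about Z, in
  (-pi, pi]. At the pole (elevation 0 or pi) the azimuth is undefined and
  is reported as 0 with an explicit degeneracy flag — silent gimbal
  artifacts are the main argument against Euler-angle sequences for this
  joint, and the flag keeps the degeneracy visible instead.
* **Torque axes**: `M_P` is reported in world axes, exactly as the network
  consumes it; a shoulder-frame view would be a convenience transform.
* **Wrench sign**: `external_wrench()` returns the wrench the *limb
  applies to the flange* (the solution of `tau_e = J' f`); the robot
  assist wrench is its reaction. The statics stage is written so that only
  the convention-invariant combination `-M_R - M_FR` matters.
* **Calibration translation**: at the reference pose (all shoulder angles
  zero) the shoulder centre sits at the sphere-fit radius vertically above
  the elbow landmark. This reconstruction is validated by round trip on
  synthetic scenes, where the generator uses the same convention.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| moving-average window | 25 | samples | 0.5 s at 50 Hz: suppresses sensor noise without distorting slow passive motion |
| sphere-fit fraction | 0.7 | — | the rotation centre drifts near end range, so only the former part of each trajectory is fitted |
| quasi-static speed gate | 0.1 | m/s | flags samples violating the static-balance assumption |
| repeatability tolerance | 0.1 | fraction of torque range | two runs of one trajectory must agree to within 10 % or the recording is invalid |
| hidden units H | 9 | — | smallest size that reliably reaches the MSE goal on the standard scene (see the sweep) |
| training goal | 0.001 | normalized MSE | evaluated on the normalized scale, where the figure is meaningful |
| max epochs | 1000 | — | cap on accepted LM steps |
| normalization range | (0.05, 0.95) | — | sigmoid outputs cannot attain 0 or 1, so mapping data onto the open sub-interval keeps every target attainable |
| split size | 500 | samples | training subset drawn uniformly without replacement |

The configured learning rate (0.01) is recorded for fidelity with common
toolbox configurations but is inert: Levenberg-Marquardt has no
learning-rate parameter, only the damping schedule. This is documented
rather than silently dropped.

## Numerical choices

* **Pseudo-inverse**: Moore-Penrose via SVD, truncating singular values
  below `1e-10 * sigma_max`. Deterministic and graceful near singular
  configurations, which are additionally flagged with a warning.
* **Sphere fit**: the algebraic (Coope-style) linearization — each point
  contributes one linear equation in the centre and in `r^2 - |c|^2` — is
  closed-form and deterministic. The test suite cross-checks it against an
  independent iterative geometric fit.
* **Moving average**: centred window with symmetric edge shrinking (the
  window shrinks to the largest centred window that fits), so the output
  has the input's length and no phase lag anywhere.
* **LM schedule**: damping `mu` starts at 1e-3, divides by 10 on each
  accepted step and multiplies by 10 on rejection, giving the conventional
  monotone accepted-step loss; training stops at the goal, the epoch cap,
  or `mu > 1e10`.
* **Weight initialization**: seeded Nguyen-Widrow-style scaling — hidden
  rows scaled to magnitude `0.7 * sqrt(H)`, biases spread uniformly —
  standard for sigmoid layers and bit-reproducible under the seed.
* **Inverse kinematics** (generator only): damped least squares with
  error-adaptive damping `1e-6 + 0.1 |err|^2`, 0.5 rad step cap, warm
  starts along the trajectory, and a fixed list of fallback starts if a
  singular local minimum is hit.

## What the synthetic generator emulates

Real measurement data for this protocol are not distributable, so the
package ships a generator that plays the role of the subject:

* a rigid limb (default 3.5 kg, centre of mass 0.28 m from the shoulder)
  on a fixed-centre ball joint;
* a parametric passive torque field: the limb's gravity torque plus a
  smooth elastic resistance that is zero at the hanging posture and grows
  toward range limits (cubic plus exponential end-range stiffening), with
  an out-of-plane cubic term and a vertical coupling term;
* a narrow, plane-coupled mid-range *engagement bump* (amplitudes 6 and
  3.5 N m, width 0.08 rad, centre shifting 1 rad per rad of plane) —
  passive structures engage over limited angular regions, and this
  localized feature gives the field the spatial complexity that real
  torque-angle data exhibit: a 5-unit network cannot represent it to the
  0.001 goal while a 9-unit network can, which is the behaviour the
  hidden-unit sweep checks;
* abduction trajectories with a monotone elevation ramp (10-120 degrees)
  and a seeded low-frequency "secondary movement" wander (5 degrees) in
  the plane of elevation;
* per-joint Gaussian external-torque noise, 0.2 N m in the standard
  scene — the order of magnitude of external-torque estimates from
  joint-torque-sensing arms;
* an optional end-stage centre drift reproducing the curvature change
  that motivates fitting the sphere on the former part only.

Every rendered sample satisfies the quasi-static balance equations to
1e-10 by construction, and the generator fixes the statically
indeterminate force decomposition (the ideal ball joint carries no force;
the robot carries the force balance minus limb gravity) — a convention
the pipeline's output provably does not depend on.

What the generator does **not** emulate: scapulothoracic and clavicular
motion (the centre is truly fixed), soft-tissue deformation under the
orthosis, velocity-dependent viscous resistance, inter-trial variability
of a human subject, and active muscle activity. Passing tests therefore
demonstrate that the *pipeline* is correct under the protocol's stated
assumptions, not that those assumptions hold for a given patient.

## Study sizes used in tests and the acceptance script

The standard scene uses two trajectories (planes of elevation 0 and 30
degrees) of 562 and 561 samples at 50 Hz — 1123 angle-torque pairs, of
which 500 train the network and 623 are held out. The hidden-unit sweep
trains H = 5 and H = 9 ten times each under different seeds. These sizes
keep a full run to seconds while leaving the qualitative conclusions
stable across seeds.

## Known limitations

* The MSE reported next to MAV is a squared-error quantity conventionally
  printed in N m alongside it; the ratio RE = MSE / MAV is therefore not
  dimensionless in a strict sense. It is implemented exactly as defined,
  and MAV is taken over the *true* torques, since the error is judged
  against the magnitude of each component.
* The default robot geometry is a generic iiwa-class chain ("default
  model"); users of a specific arm should supply their own
  `robot_params()` or YAML config.
* The network architecture is fixed at 2-H-3 with sigmoid activations;
  there is no validation-based early stopping (goal and epoch caps only)
  and no architecture search beyond the H sweep.
* Predictions are only trustworthy inside the measured posture range; the
  sigmoid output bounds predictions to the output normalizer's range, so
  extrapolation saturates rather than diverges.
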