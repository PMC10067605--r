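---
title: "Methods: active inference reaching with flexible intentions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active inference reaching with flexible intentions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flexreach)
```

## The model

The agent controls a planar limb with three revolute joints (neck/torso,
shoulder, elbow) anchored at a fixed neck inside a 128 x 96 pixel camera
frame whose coordinates coincide with workspace coordinates. The world state
is the joint-angle vector $\theta$ with noisy velocity-level motor control,
$\dot\theta = a + w_a$, and hard clamping at the joint limits.

The agent's internal state is a generalized belief
$\tilde\mu = \{\mu, \mu'\}$ over nine joint angles partitioned into three
blocks: the arm posture $\mu_a$, the target posture $\mu_t$ (the
configuration whose hand position is the target centre - an affordance-style
encoding), and a memorized home-button posture $\mu_h$.

Two sensory channels generate predictions from the belief:

* proprioception predicts the arm block directly, $g_p(\mu) = \mu_a$;
* vision predicts the rendered scene $g_v(\mu_a, \mu_t)$ through a visual
  generative model whose reverse-mode gradient $\partial g_v^\top$ pulls
  image errors back into the belief space, implicitly performing a
  kinematic inversion.

Intentions are functions of the current belief that predict a plausible
future belief. The stock pair is linear: *reach* sets the arm block equal to
the target block, *home* sets it equal to the home block; both leave the
other blocks untouched, so intention prediction errors are structurally zero
outside the arm block. The intention errors enter the first-order belief
dynamics as attractors with gain $\lambda$ and balance
$(1-\beta, \beta)$:

$$
\dot\mu = \mu' + \epsilon_s, \qquad
\dot\mu' = -\mu' + \lambda\left[(1-\beta)\,e_{it} + \beta\,e_{ih}\right],
$$

where $\epsilon_s$ is the precision-weighted sensory contribution
($(1-\alpha)$ proprioceptive, $\alpha$ visual on the arm block, $\pi_{vt}$
visual on the target block, nothing on the home block). The order-0 backward
dynamics term is truncated by default (the forward first-order error acts as
the attractor force); `belief_update(backward_term = TRUE)` restores it for
experimentation. Action integrates the proprioceptive prediction error
through the reflex-arc pathway, $\dot a = -\Delta_t (1-\alpha)\,
\varepsilon_{sp}$, so $\alpha = 1$ freezes action entirely; the alternative
*full* scheme maps the complete weighted sensory contribution to the
actuators through the (pseudo)inverse of the proprioceptive map.

An alternative, equivalence-tested update path (`belief_update_neural()`)
implements the same computation with explicit prediction-error units relaxed
to their fixed points. The two paths coincide exactly at unit precisions
with $\lambda = 0$; in general the error units converge to
precision-*divided* errors while the direct form applies
precision-*multiplied* errors, and the neural form includes the backward
dynamics term the direct form truncates. We treat the direct form as
canonical and document rather than resolve the convention difference.

## Visual generative models

Two interchangeable implementations satisfy the `vm_decode()` /
`vm_pullback()` contract.

**Convolutional VAE** (`train_visual_model()`): the decoder maps the 6-d
(arm, target) latent through one dense layer, two transposed convolutions
(kernel 8, stride 4) and two smoothing convolutions (kernel 3) to the
3 x 128 x 96 scene; the encoder (two convolutions plus a dense readout)
regresses the normalized angles from the image. Training is supervised:
the decoder reconstructs the rendered scene from the true normalized angles
jittered by the fixed recognition-density standard deviation `encoder_sd`,
and the encoder minimizes a latent regression loss (weight `latent_weight`,
default 100, balancing a ~10^2-pixel reconstruction error scale against a
6-d latent error). Optimization is Adam (`lr = 1e-3`, batch 32), implemented
with im2col + GEMM convolutions and hand-written reverse mode; the pullback
is therefore the exact adjoint of the decode (finite-difference checked).
The latent jitter is the mechanism behind the recognition-variance effects:
more jitter produces blurrier decoded blobs and smoother, longer-range
gradients, at the cost of reconstruction fidelity.

**Analytic soft rasterizer** (`analytic_visual_model()`): renders the limb
as logistic-edged capsules (`blur_limb`, default 2 px) and the target as a
logistic-edged disc (`blur_target`, default 14 px), with an exact analytic
adjoint through the capsule/disc distances and the kinematic chain. This
model plays the role of a well-trained, high-variance decoder: the wide
target edge is what gives the belief usable gradients when the estimated
and observed target are tens of pixels apart, exactly as a neural decoder's
globally-supported gradients do. Three further choices matter:

* *No occlusion in the decode* (`occlusion = FALSE` by default). An
  occlusion-aware soft decoder makes the target gradient try to hide the
  predicted blob behind the limb (both start at the hand), which traps the
  target belief at trial start. The hard generative-process render always
  occludes; the decoder predicts the target plane unoccluded, trading a
  little fidelity for an informative gradient field. A learned decoder
  blurs the occlusion boundary so heavily that it behaves the same way.
* *Frame suppression* (`frame_pad`, default 60 px). The rasterizer predicts
  on an unbounded plane while the camera observes a finite frame. Without
  accounting for the prediction mass outside the frame, the in-frame
  gradient of a near-edge blob is asymmetric and the target belief drifts
  toward the boundary. `vm_frame_term()` adds the gradient of the squared
  prediction over a band outside the frame (structural zero observations),
  restoring an unbiased equilibrium. The exported `vm_pullback()` remains
  the exact adjoint of the in-frame decode; the suppression term is kept
  separate and added by `sensory_contribution()`.
* *Joint-range prior* (`range_prior`, default 1). Beliefs are
  unconstrained, and smooth extrapolation lets target inference settle on
  out-of-limit kinematic branches, driving the arm into a joint stop. A VAE
  trained only on in-range postures carries this prior implicitly in its
  decoder; the rasterizer needs it explicitly: belief components outside
  the limits are pulled back with gain `range_prior`.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.5 | proprioceptive (1-alpha) vs visual (alpha) arm precision |
| `beta` | 0.1 | reach vs home intention balance during movement |
| `lambda` | 0.5 /step | attractor gain (movement vigor); 0 during the delay |
| `pi_vt` | 10 | target-block visual precision (larger than alpha, which also matches the observed advantage of a high target precision) |
| `pi_vh` | 0 | home block is invisible and memorized |
| `visual_gain` | 5e-4 | per-pixel visual precision converting summed image errors to belief units |
| `belief_lr` | 0.15 | belief integration step |
| `dt_action` | 1 | action integration constant (use ~0.1 for the full control scheme, whose input has a much larger magnitude scale) |
| `sigma_p, sigma_v, sigma_a` | 0.01 rad, 0.01, 0.02 rad/step | sensor and motor noise |

`visual_gain` and `pi_vt` were calibrated jointly on the noiseless system so
that (i) the target belief converges within the 100-step delay from any
grid target without overshoot and (ii) the sharp limb-edge pullback (whose
raw magnitude is ~20x the target blob's) does not destabilize the
arm-belief/action loop. `belief_lr = 0.15` was chosen by eigenvalue
analysis of the linearized belief-action loop: the loop is an
integral-controlled double integrator whose slow mode at step 0.1 is weakly
damped (spectral radius about 0.97 per step) and visibly amplifies motor
noise in the final approach; 0.15 brings the radius down while preserving
the ordering of the sensory-feedback conditions. Anti-windup resets an
action component when its joint clamps at a limit (the stored velocity is
likewise zeroed), preventing integrator windup when inference briefly
favors a posture at the edge of the range.

## Tasks and the generative world

`run_delayed_reaching()` implements the reference protocol: hand on the
home button (on the body midline at 45% of the limb length, chosen so that
the closest grid target is well outside the 10 px criterion), belief
initialized at that posture in all three blocks, a 3 x 3 target grid
(depths 26/36/46 px from the resting shoulder at 60/90/120 degrees,
mirror-symmetric about the midline, all reachable and fully inside the
frame), 100 delay steps with $\lambda = 0$, 300 steps total, 100
repetitions per target. The delay is implemented by zeroing the intention
gain (the alternative, zeroing proprioceptive precision, is available as a
trial-level choice but is not tested against reference numbers). Movement
onset policies: `immediate`, `fixed` (the default delay), and `dynamic`
(movement starts once the target-belief update norm stays below 0.01 for 5
consecutive steps). `run_tracking()` drives a target at 0.1 px/step in a
uniformly random direction with elastic reflection at the workspace
borders, with belief and action inferred continuously from the first step.

Random target sets (`sample_reachable_targets()`) cover the operational
space: hand positions uniform over the reachable workspace, accepted when
damped-least-squares inverse kinematics finds a within-limits posture and
when at least half of the target disc is visible past the limb in the
start posture. The visibility constraint defines the task's operational
space: the camera is positioned for full vision of peripersonal targets,
and spots tucked behind the torso are not legitimate targets (and are
unperceivable in principle).

The simulated world is deliberately minimal: no masses, friction, delays,
or 3-D projection; pixel noise is i.i.d. Gaussian, proprioception is a
noisy angle readout. Passing tests therefore demonstrate the inference and
control machinery under these idealized conditions, not robustness to the
sensorimotor complexities of real limbs.

## Numerical choices

* Soft-edge supports are truncated at 7.5 blur units (logistic value
  ~5.5e-4) consistently in the decode, the pullback and the suppression
  band, so the adjoint property survives truncation exactly.
* The frame-suppression band is evaluated on a 2 x 2 subsampled grid
  (weight 4); the suppression force is a smooth functional of the blob
  position and tolerates coarse quadrature.
* The trial loop is implemented twice: a fast fused C++ runner (observation,
  prediction, error, noise and pullback in one pass over the image, PCG32 +
  ziggurat noise) and a reference R composition of the exported module
  functions. The two are equivalence-tested to 1e-10 on noiseless trials;
  stochastic trials are reproducible per engine given the seed.
* Error-unit relaxation (`belief_update_neural()`) uses rate 0.2 for up to
  5000 iterations; with precisions well below 1 the fixed-point approach is
  slow, and non-convergence raises a typed condition rather than returning
  a partial update.
* Divergent trials (any belief component beyond 10 joint ranges, or
  non-finite) abort with a flag and count as failures in all metrics.
* Inverse kinematics (generative-process side only) is damped least squares
  with multiple fixed starts; the agent itself never inverts kinematics.

## Metric conventions

Success is judged at trial end (final distance within the criterion,
boundary inclusive); reach/perception *time* is the first step at which the
criterion holds, counted as steps needed (0 if it holds immediately);
*stability* is the standard deviation of the distance from that step to the
end, defined only for successful trials; the arm-belief error maps the arm
belief through the forward model and takes the L2 distance to the true hand
position at trial end. Confidence intervals are normal-approximation at 95%
(bootstrap available and cross-checked).

## Problem sizes used by the tests

The test suite runs the full protocol shapes at reduced counts chosen as
the package's standard quick-validation sizes: 12 repetitions per grid
target per feedback condition, 60 random targets per sweep level, 10
tracking trials, VAE trainings of 60-900 samples for 2-3 epochs with
reduced channel counts, and a 200-target noiseless-baseline run. The
acceptance script (`scripts/acceptance.R`) runs the full 900-trial protocol
per condition. All drivers scale to the full sizes (1000-target sweeps,
20000-sample / 100-epoch training) unchanged.

## Known limitations

* With the spec'd noise defaults the proprioception-only condition is only
  mildly handicapped (proprioceptive noise of 0.01 rad moves the hand well
  under the 10 px criterion), so the accuracy gap between feedback
  conditions is small and its sign is not guaranteed at moderate trial
  counts; the stability and belief-error advantages of vision are robust.
* The full-control scheme needs a smaller action constant than the
  reflex-arc scheme (see above); with the rasterizer's sharp limb edges the
  default `dt_action = 1` destabilizes it.
* The dynamic onset policy can fail to trigger on noisy trials whose
  target-belief update norm never stays below threshold; this is logged,
  not fatal.
* The neural update path is a demonstration of equivalence, not an
  optimized engine; it relaxes image-sized error-unit populations by
  fixed-point iteration.
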