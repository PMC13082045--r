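---
title: "Predicting the energetic effect of exotendons on running: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the energetic effect of exotendons on running: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(exotendon)
```

An exotendon is a passive extension spring connecting a runner's two
shoes, characterized by a stiffness $k$ (N/m) and a slack length $l$
(m, often quoted as a percentage of leg length). Because the spring
stores energy as the feet separate and returns it as they approach, a
well-chosen $(k, l)$ can reduce the metabolic cost of running. This
package implements a simulation pipeline that predicts the energetic
effect of candidate designs at 4 m/s, a design-space sweep over a
$5 \times 5$ stiffness-by-slack grid, and the measurement pipeline used
to evaluate designs experimentally (indirect calorimetry, marker-derived
spring tension, paired statistics) — exercised end to end on synthetic
data with known ground truth.

## The musculoskeletal model

The skeleton is a planar rigid-body tree with 20 generalized
coordinates: a pelvis-ground joint with two translations and three
rotations (tilt active; list and rotation are locked out-of-plane
coordinates carried as inertially decoupled rotations so that the
coordinate count and mass matrix stay complete), one-rotational hip,
knee, ankle, metatarsophalangeal (MTP), shoulder and elbow joints per
side, and a three-rotational lumbar joint (extension active). Segment
masses, lengths and inertias come from standard anthropometric
regressions scaled to a 1.78 m, 73 kg runner; the zero-pose leg spans
0.92 m. Sign conventions: x forward, y up, hip/shoulder flexion
positive, knee flexion negative, ankle dorsiflexion positive.

Dynamics are evaluated by a vectorized planar Newton–Euler recursion:
`inverse_dynamics()` returns $M(q)\ddot q + c(q,\dot q) - J^\top F -
\tau$ for whole trajectories at once, `mass_matrix()` and
`bias_forces()` expose the implicit form used by the collocation
defects, and `simulate_passive()` integrates unforced motion (used by
the energy-conservation oracle: drift below $10^{-9}$ relative over a
1 s double-pendulum swing).

Eighteen Hill-type muscle–tendon units actuate the legs (nine groups
per side: iliopsoas, gluteus maximus, rectus femoris, biarticular
hamstrings, vasti, biceps femoris short head, gastrocnemius, soleus,
tibialis anterior); the arms and lumbar joint are torque-driven.
Maximum isometric forces are doubled relative to generic values and the
active force–length operating range is widened by 50%, reflecting
trained runners. The widening is applied symmetrically about the
optimal fiber length — `active_force_length(1 + d, w)` equals the
unwidened curve at `1 + d/w` — because nothing in the force-capacity
argument distinguishes the ascending from the descending limb. Muscle
paths are coordinate-dependent moment-arm polynomials with reference
lengths anchored at a mid-stride posture (hip 0.25, knee −0.8, ankle
0.05 rad) so fibers operate around their optimum over the stride. The
force–velocity, passive and tendon curves are smooth exponential/
log-stretch forms with every constant in `muscle_curve_constants()`;
exponents are capped so optimizer probes far off the gait manifold stay
finite. Activation dynamics are a smooth first-order lag
(tanh-blended time constant, 15 ms activation / 60 ms deactivation).

Metabolic rate uses a smoothed Bhargava-style model — activation heat
(40 W/kg of muscle mass), maintenance heat (74 W/kg scaled by the
active force–length multiplier), shortening heat (0.25 of fiber force
times shortening speed) and mechanical work rate, clamped smoothly at
zero. Muscle masses derive from the (doubled) isometric forces via a
specific tension of 0.6 MPa and density 1059.7 kg/m³. The reported
simulation cost is the muscle-only ("net") average rate in W/kg;
`cost_gross_wkg` adds a whole-body basal rate of 1.2 W/kg. Percent
changes between conditions are computed on the net cost by default
(both are emitted), since the basal term is identical across conditions
and only dilutes contrasts.

Foot–ground contact uses four smoothed Hunt–Crossley spheres per foot
(heel, two at the MTP, forefoot) with the standard parameter set
(stiffness 10 MPa entering a Hertz $d^{3/2}$ law, dissipation 1.0 s/m,
friction coefficients 0.8/0.8/0.5, transition velocity 0.2 m/s, radius
0.035 m). Penetration is smoothed over 0.1 mm so the force is C1
across lift-off; tangential force is a tanh-regularized Coulomb law
plus viscous term. The "two spheres at the metatarsophalangeal joint in
the rearfoot" placement is ambiguous as stated; both are placed at the
MTP joint on the calcaneus segment.

The exotendon is a linear extension spring between calcaneal anchor
points: tension $= k \max(0, d - l)$ with $d$ the 3-D anchor distance.
The planar model has no mediolateral coordinate, so a constant 0.25 m
foot separation supplies the out-of-plane component. Inside the
optimizer a softplus-smoothed tension (width 1 mm, error bounded by
$k \cdot w \log 2$) keeps the objective differentiable; every analysis
path uses the exact piecewise law. Slack lengths follow the
percent-of-leg-length convention with $L = 0.92$ m (the "medium"
design, $k = 120$ N/m at 25%, is 0.23 m); an alternative absolute
figure of 0.29 m appears in the source literature's summary text and is
recorded as unreconciled rather than resolved.

## The tracking optimization

Assisted and natural running are predicted with a muscle-driven
tracking problem over half a gait cycle with left–right symmetry,
minimizing

$$ J = \int_{t_i}^{t_f} \Big[ \sum_i w_{kin} (q_i - \bar q_i)^2
  + \sum_i w_{grf} (\mathrm{GRF}_i - \overline{\mathrm{GRF}}_i)^2
  + \sum_i w_{act} a_i^2 + \sum_i w_{met} \dot E_{met,i}^2 \Big] dt $$

with $w_{kin} = 10^{-6}$, $w_{grf} = 14$ (on body-weight-normalized
forces), $w_{act} = 8.0$ and $w_{met} = 4 \times 10^{-5}$, so muscle
effort dominates. Tracking differences are squared (a least-squares
tracking term; an unsquared difference has no meaningful minimum), and
the sums run over tracked coordinates, GRF components (vertical and
fore–aft per foot; the model is planar) and muscles respectively.

**Transcription.** Rather than transcribing states and controls on a
dense mesh for a sparse NLP solver, the problem is posed as
inverse-dynamics-based collocation over a reduced parameterization:

* Coordinate trajectories are the reference plus periodic Fourier
  deviations. Mirrored limb pairs (hip, knee, ankle, shoulder, elbow)
  share one coefficient set applied to the right side and, phase-shifted
  by half a stride, to the left; pelvis and lumbar deviations have
  half-stride period. This builds the half-cycle symmetry and the
  average-speed constraint into the decision space exactly.
* At each mesh node the smoothed contact and exotendon forces follow
  from the candidate kinematics, inverse dynamics gives the required
  generalized forces, and a static muscle-redundancy problem (weighted
  least squares over activations with box bounds and an active-set
  pass) resolves the leg torques into activations. Excitations equal
  activations (static-optimization approximation; the first-order
  activation dynamics are implemented and tested as their own
  operation but not imposed as a path constraint at this mesh
  resolution).
* Torque that no admissible activation can produce (reserves), and the
  residual forces at the unactuated pelvis coordinates, are penalized
  with body-weight-normalized weights (`w_residual = 200`,
  `w_reserve = 50`). The returned solution reports their peaks;
  dynamics at actuated coordinates are satisfied identically by
  construction, and the residual actuators play the same role as
  residual/reserve actuators in standard musculoskeletal tracking
  pipelines.

Every term is a square, so the transcribed problem is a nonlinear
least-squares problem solved with Levenberg–Marquardt
(`minpack.lm::nls.lm`) under per-coefficient path bounds that keep
deviations in a physiological corridor (0.35 rad for leg coordinates,
6 cm for pelvis translations, 0.25 rad for pelvis tilt and lumbar, 0.6
rad for arms). The forward-difference step of the numerical Jacobian is
kept large enough (`epsfcn = 1e-4`) to average over the redundancy
active-set kinks, and a bounded number of restarts polishes the
solution. On this landscape the solver's stationarity is at about the
1% relative level — re-solving from a returned solution can still
improve $J$ by a few tenths of a percent — so absolute objective values
should be read at that resolution; condition contrasts (percent
changes) are always computed between solves at identical settings. The
initial guess is the reference itself (all deviations zero); the solve
is deterministic for a given configuration.

Default problem sizes: 10–15 mesh intervals per half cycle, 3 leg and
3 pelvis harmonics (62 decision variables); one solve takes tens of
seconds. Quadrature is trapezoidal on the node grid, which is
spectrally accurate for the smooth periodic integrands (the
10×-finer-grid oracle agrees to well under 0.1%).

**Stride duration.** Each design is simulated at several stride
durations (90/95/100/105% of natural); `rescale_reference()`
time-normalizes the reference, preserves the running speed (stride
length scales with duration) and keeps the GRF shapes so the
impulse–momentum balance carries over. The energetically best converged
stride is kept per design — and for the natural baseline too, so
percent changes compare optima to optima.

## The synthetic reference gait

No external motion-capture data are bundled; `generate_reference_gait()`
constructs the tracked half-cycle from first principles:

* a task-space ankle path with stationary stance (heel-to-toe roll
  confined to the lightly loaded edges of stance), an exact
  metatarsal-pivot geometry through push-off, C2-smooth periodic
  swing-recovery windows, and a stance penetration profile;
* two-link inverse kinematics for hip and knee with a smooth soft cap
  on leg extension (a hard clamp puts near-impulsive knee accelerations
  into the reference);
* reference GRFs taken from the model's own contact law evaluated on
  those kinematics, with the penetration depth iterated until the
  vertical impulse balances body weight over the stride (within 0.5%);
* a pelvis path obtained by double-integrating those contact forces and
  placing the pelvis so the whole-body center of mass follows the
  integral (Newton's second law; ballistic flight), iterated jointly
  with the previous step.

The duty factor defaults to 0.30: with a 0.92 m leg and a stationary
stance foot, the hip travel at a 0.35 duty and 4 m/s cannot be spanned
without over-extension, so 0.30 is used and recorded as a deliberate
choice. The generator is a pure function of its parameters and seed; a
`jitter` argument perturbs the shape harmonics deterministically to
emulate between-subject variability.

What this emulates — periodic sagittal running kinematics with
consistent single-peak stance forces — and what it does not: real
impact transients, soft-tissue dynamics, three-dimensional motion,
measurement noise in marker-derived joint angles, or between-stride
variability. Tests that pass on this reference demonstrate the
machinery (tracking, redundancy, sweep logic, percent-change
accounting), not predictive validity for any particular runner.

## Scaled-down simulation behavior

At the desk-scale mesh the absolute cost of the simulated natural gait
(about 23 W/kg muscle-only) is higher than treadmill-measured running
costs: the synthetic reference is more violent than a human stride
(deeper knee flexion, sharper stance peaks) and the residual-actuator
corridor adds effort. Peak spring tensions reproduce the reported
ordering and magnitudes — short-stiff ~221 N (largest), long-stiff
~166 N, medium-original ~97 N, long-compliant ~21 N (smallest). The
energetic predictions, however, compress and partly invert the
full-scale picture: across the 5×5 grid the largest predicted saving is
about −3.7% for a light spring (k = 60 N/m, slack 12.5%),
medium-original saves about −1%, and the stiffest designs *cost* energy
(+3 to +5%). At this scale the reduced Fourier decision space cannot
re-coordinate the stride deeply enough for stiff springs to pay off,
so their always-taut tension mostly adds torque demand at near-fixed
kinematics. The percent changes are reported exactly as computed; they
are not calibrated toward any external figure.

## The experimental analysis pipeline

* **Calorimetry.** Breath-by-breath gas exchange converts to power via
  the Brockway equation ($16.58\,\mathrm{kJ/L\,O_2} +
  4.51\,\mathrm{kJ/L\,CO_2}$; the specific equation is an assumption
  recorded in the configuration), time-weight averaged over the final
  minute, normalized by body mass, with the standing baseline
  subtracted. Trials with mean RER > 1.0 over the same window are
  excluded; excluded conditions propagate as missing values, and a
  subject whose natural trial is excluded drops from comparisons
  entirely (listwise).
* **Marker tension.** The 3-D Euclidean distance between the two shoe
  markers (200 Hz) gives the spring length; tension is the exact
  piecewise law applied pointwise. Trials are segmented at ipsilateral
  foot strikes (vertical-position minima with a prominence threshold
  and minimum-period guard), gaps up to 5 samples are bridged linearly
  and longer gaps drop the containing cycle, profiles are
  time-normalized to 101 points and averaged across cycles within each
  runner and then across runners. Time-normalization before averaging
  is an assumption, recorded here.
* **Statistics.** Within-subject differences are tested with
  Shapiro–Wilk, compared by two-sided paired t-tests, and
  Bonferroni-corrected — across four comparisons for the in-lab family
  and three for the track family — with significance at corrected
  p < 0.05. Zero-variance differences yield a degenerate-test warning
  with p reported as 1.

The calorimetry generator injects known multiplicative condition
effects on a per-subject natural net power drawn from N(10, 1) W/kg
(a configured default; the measured in-lab deltas imply a higher
natural cost at 4 m/s, but effects are specified in percent so
percent-change recovery is unaffected). Because the on-transient and
averaging window are identical across conditions, injected effects
pass through the pipeline exactly in the noiseless limit; with
log-normal breath noise (4% SD) the mean recovered effect is within
one percentage point over replicates, and the corrected type-I error
of the full workflow on null datasets sits in the nominal band.

## Numerical choices and degenerate inputs

Internal units are SI and radians; conversions happen only in the TRC
and STO/MOT readers/writers (mm and degree headers respected; readers
reject malformed or inconsistent headers with line numbers). Gait-cycle
zero is the first upward crossing of 5% body weight by the vertical
GRF. Ties in design ranking break by grid order. Coincident exotendon
anchors are handled by an epsilon-regularized direction. Non-converged
stride durations are excluded from per-design minima; a design with no
converged stride is marked failed, never silently dropped; a
non-converging natural baseline is a configuration error.

## Known limitations

Planar dynamics without mediolateral balance; rigid-tendon muscle
kinematics inside the optimizer (tendon compliance is modeled and
tested at the MTU level); static-optimization muscle recruitment
(no activation-rate path constraint at coarse meshes); residual
actuators at the pelvis absorb the remaining dynamic inconsistency of
the synthetic reference; the reduced Fourier decision space cannot
represent discontinuous coordination changes. These are the main
reasons the scaled-down percent-change predictions should be read
qualitatively, while the measurement-side pipelines (tension,
calorimetry, statistics) are exact to their stated tolerances.
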