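# exotendon

Simulation-guided design of exotendon springs for running.

An **exotendon** is a passive extension spring connecting a runner's two
shoes, with two design parameters: stiffness *k* (N/m) and slack length
*l* (m, or % of leg length). It can reduce the energetic cost of running
by storing energy as the feet separate and returning it as they swing
back together — but which (*k*, *l*) helps, and by how much, depends on
speed and coordination. Testing many designs on human runners is slow
and exhausting; this package implements the alternative: predict the
energetic effect of candidate designs with muscle-driven simulation,
sweep the design space, and carry only a few designs to (here,
synthetic) experimental evaluation.

The package is organized as an analysis workflow (numbered scripts under
`analysis/`) over a library of tested components:

* **Planar musculoskeletal model** — a 20-coordinate sagittal-plane
  skeleton (pelvis 3 rotations + 2 translations; hip, knee, ankle,
  metatarsophalangeal, shoulder, elbow per side; 3-rotational lumbar),
  scaled to a 1.78 m / 73 kg runner, with 18 Hill-type muscle–tendon
  units (doubled maximal forces, active force–length range widened by
  50%), smooth Bhargava-style muscle energetics, four smoothed
  Hunt–Crossley contact spheres per foot (10 MPa, dissipation 1.0 s/m,
  friction 0.8/0.8/0.5, radius 0.035 m), and the exotendon as a linear
  spring between calcaneal anchors.
* **Tracking optimization** — a muscle-driven simulation over half a
  gait cycle with left–right symmetry, minimizing

  *J* = ∫ [ Σ w<sub>kin</sub>(q − q̄)² + Σ w<sub>grf</sub>(GRF − ḠRF)² +
  Σ w<sub>act</sub> a² + Σ w<sub>met</sub> Ė²<sub>met</sub> ] dt

  with w<sub>kin</sub> = 10⁻⁶, w<sub>grf</sub> = 14 (body-weight
  normalized), w<sub>act</sub> = 8.0, w<sub>met</sub> = 4×10⁻⁵,
  transcribed by inverse-dynamics-based collocation over a periodic,
  symmetry-respecting Fourier parameterization and solved as a nonlinear
  least-squares problem (Levenberg–Marquardt).
* **Design sweep** — stiffness {30, 60, 120, 180, 240} N/m × slack
  {6.25, 12.5, 25, 37.5, 50}% of a 0.92 m leg (25 designs), each at
  stride durations 90–105% of natural, keeping the energetically best
  stride; percent change vs simulated natural running; per-design spring
  tension profiles over the gait cycle.
* **Experimental pipeline** — breath-by-breath calorimetry to net
  metabolic power (Brockway equation, final-minute average, standing
  baseline subtraction, RER > 1.0 exclusion), marker-derived spring
  tension (tension = k × stretch from 3-D marker distance, per-cycle
  101-point profiles, cycle- then runner-averaged), and the paired
  statistical workflow (Shapiro–Wilk, paired t, Bonferroni over 4 in-lab
  / 3 track comparisons).
* **Synthetic data generators** — every input the pipeline consumes,
  with ground truth: a dynamically consistent periodic reference gait at
  4 m/s (contact-model GRFs, impulse-balanced, COM-consistent pelvis
  path), two-marker shoe recordings at 200 Hz encoding known tension
  profiles, breath-by-breath calorimetry with injected condition
  effects, and paired 5-km track sessions.

## Worked example

Predict the effect of the previously published "medium" design
(k = 120 N/m, slack 25% of leg length) on the cost of running at 4 m/s:

```r
library(exotendon)

model <- build_default_model()                   # 20-DOF planar skeleton
ref   <- generate_reference_gait(model, speed = 4, stride_duration = 0.7,
                                 n_samples = 31, seed = 1)
cfg   <- ocp_config(mesh = 10, n_harm_pelvis = 3)

natural <- solve_tracking(build_tracking_problem(model, ref, NULL, cfg))
spec    <- exotendon_preset("medium-original")
assisted <- solve_tracking(build_tracking_problem(model, ref, spec, cfg))

natural$cost_wkg                        # 23.212  (W/kg, muscle-only)
assisted$cost_wkg                       # 23.346
percent_change(assisted$cost_wkg, natural$cost_wkg)   # +0.57 (%)
extract_tension_profile(assisted, spec)$peak          # 97.0 (N)
```

The two costs are average muscle metabolic rates over the stride in
W/kg; `percent_change` is the design's predicted effect relative to
natural running (negative = savings), and the tension profile is the
spring force over 0–100% of the gait cycle starting at heel strike. At
this desk-scale mesh the four named designs reproduce the qualitative
tension ordering (short-stiff ≈ 221 N peak, largest; long-compliant ≈
21 N, smallest). Savings appear once the stride duration is also
optimized (the full sweep in `analysis/03_design_sweep.R` finds its
optimum at a light spring, k = 60 N/m at 12.5% slack, −3.7%), and are
much smaller than full-scale simulation studies report — see the
methods vignette (`vignettes/exotendon-methods.Rmd`) for why.

The full workflow runs as:

```sh
Rscript analysis/01_reference_gait.R      # synthetic tracked gait
Rscript analysis/02_natural_simulation.R  # natural-running baseline
Rscript analysis/03_design_sweep.R        # 5x5 grid x 4 stride durations
Rscript analysis/04_tension_profiles.R    # simulated spring tensions
Rscript analysis/05_synthetic_experiment.R# calorimetry + marker pipelines
Rscript analysis/06_statistics.R          # paired stats, Bonferroni
```

Each stage prints what it found and writes tables under `results/`.
Stage 03 solves ~100 tracking problems and takes on the order of an
hour; everything else finishes in minutes.

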