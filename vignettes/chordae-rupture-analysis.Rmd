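---
title: "Chordae rupture biomechanics and regurgitation energetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chordae rupture biomechanics and regurgitation energetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chordaemr)
```

# Scope

Rupture of the mitral chordae tendineae disconnects part of the posterior
leaflet from the papillary muscles, causes leaflet prolapse and mitral
regurgitation (MR), and redistributes the systolic load among the surviving
chordae. Full fluid–structure interaction (FSI) simulation of this process
requires patient-specific geometry and days of cluster time. `chordaemr`
implements the *analysis layer* of such a study at desk scale:

* the constitutive models — a fiber-reinforced anisotropic hyperelastic
  strain-energy function for the leaflets and an incompressible Ogden law
  for the chordae;
* a tension-only truss model of the chordae apparatus with seven
  progressive rupture scenarios, and the aggregation of chord tensions into
  per-group and per-papillary-muscle forces;
* quantification of MR from transvalvular flow waveforms (closing/leakage
  volume split, regurgitant fraction, severity grading);
* pressure–volume (PV) loop energetics (stroke work, forward stroke work,
  pressure–volume area, left-ventricular efficiency);
* a synthetic waveform and geometry generator so the entire pipeline is
  testable without any patient data.

The FSI solver itself, image segmentation, 3D leaflet stress fields and
regurgitant jet hydrodynamics are out of scope.

# Leaflet constitutive model

Leaflet tissue is modeled as a nearly incompressible, fiber-reinforced
hyperelastic solid with strain energy

$$W = C_{10}\{\exp[C_{01}(\bar I_1 - 3)] - 1\}
 + \frac{k_1}{2k_2}\sum_{i=1}^{2}\left\{\exp\!\left(k_2\left[\kappa \bar I_1
 + (1-3\kappa)\bar I_{4i} - 1\right]^2\right) - 1\right\}
 + \frac{1}{D}(J-1)^2,$$

where $\bar I_1$ and $\bar I_{4i}$ are the deviatoric strain invariants of
the two fiber families, $J = \det F$, and $C_{10}$ (MPa), $C_{01}$, $k_1$
(MPa), $k_2$, $\kappa \in [0, 1/3]$ and $D$ (MPa$^{-1}$) are material
constants. The matrix term uses the exponential form exactly as written
above (not the polynomial Mooney–Rivlin form some dispersion models use).
$\kappa = 1/3$ makes the fiber contribution isotropic; the package verifies
that stress then becomes independent of the fiber directions.

Two modelling choices were genuinely open:

* **Fiber tension switch.** Whether dispersed collagen fibers should bear
  compressive load is not fixed by the energy above. The package follows
  the standard convention that a fiber family contributes only while its
  dispersed pseudo-invariant argument
  $\kappa\bar I_1 + (1-3\kappa)\bar I_{4i} - 1$ is positive (collagen
  cannot push); the switch can be disabled via
  `mhgo_params(..., fiber_tension_only = FALSE)`.
* **Fiber directions.** Directions live in a local leaflet frame; the
  package uses two symmetric families at $\pm\theta$ about the local
  circumferential axis, with $\theta$ configurable
  (`fiber_directions()`).

Stress is computed analytically: $S = 2\,\partial W/\partial C$, pushed
forward to $\sigma = J^{-1} F S F^T$. `material_verification()` checks the
analytic first Piola–Kirchhoff stress against a central finite-difference
gradient of the energy (step $10^{-6}$ relative) on random admissible
deformation states; the agreement is at round-off level (~$10^{-10}$
relative, far below the $10^{-5}$ bound the test suite enforces).

Material constants are **user inputs**: `example_materials()` ships a
documented set in the physiological ballpark for demonstrations and tests,
explicitly *not* fitted experimental values.

# Chordae model and rupture scenarios

Chordae are tension-only cables. Each truss segment carries the axial force
of an incompressible uniaxial Ogden bar,
$F(\lambda) = A_0 \sum_p \mu_p (\lambda^{\alpha_p - 1} -
\lambda^{-\alpha_p/2 - 1})$ for stretch $\lambda > 1$ and zero otherwise;
a one-term model with $\alpha = 2$ reduces to the neo-Hookean
$\mu(\lambda - \lambda^{-2})$, which the tests use as a closed-form check.

`build_network()` constructs an idealized apparatus because the real
geometry is patient-specific and unavailable: a D-shaped annulus in the
$z = 0$ plane (ventricle at $z < 0$, millimetres), leaflet insertion points
on one anterior arc and three posterior scallop arcs (P1 anterolateral, P2
central, P3 posteromedial), and 17 chordae origin nodes on two papillary
tips. Origin and insertion counts per chordae group (anterior marginal and
strut; posterior marginal, intermediate and basal) follow the reference
structure in `chordae_count_spec()`; cross-sections default to
0.71/2.05/0.38 mm$^2$ for basal-intermediate/strut/marginal chordae. Chords
are discretized into elements of ~1.5 mm average length, at most 10 per
chord. Each default chord runs unbranched from an origin node to a single
insertion (several chords share each origin); the solver itself handles
arbitrary topologies, including forked chords, as the two-chord "V" test
shows. Seeded jitter makes each network reproducible.

The seven rupture scenarios follow the clinical progression: isolated
scallop prolapse removes all marginal and intermediate chordae of one
posterior scallop; partial double prolapse adds the P2-adjacent half of a
neighbouring scallop; total double prolapse additionally removes the basal
chordae of both scallops. The exact removed-element sets are not itemized
in any source, so `scenario_segments()` implements this narrative and
accepts an explicit override list.

## Static equilibrium solver

`solve_static_tensions()` finds nodal equilibrium of the tension-only
network under a load case by Newton's method with: 10 equal load
increments; a consistent tangent (axial material stiffness for taut
segments plus geometric stiffness); a small diagonal regularisation
($10^{-7}$ of the largest diagonal entry) so slack-segment null directions
stay solvable; a per-iteration cap on the largest nodal move (half the mean
element length) with a backtracking line search, because the steep Ogden
law makes uncapped Newton steps overshoot; convergence at a residual force
norm below $10^{-8}$ of the applied load norm, at most 50 iterations per
increment. Mechanisms produce a singularity error naming the node;
non-convergence raises an error carrying the residual history.

The default load case converts a peak-systolic transmitral pressure
(120 mmHg; 1 mmHg = 133.322 Pa) into per-insertion pulls via tributary
leaflet areas (700 mm$^2$ total, weighted so the load-bearing basal and
strut chordae shield the most leaflet area). The load direction at each
insertion is the local chord axis: the leaflet hands its pressure load to a
chord along the chord's line of action. This replaces the FSI pressure
field, which is out of scope; consequences are that group forces reflect
the tributary-area model rather than leaflet mechanics, and rupture
redistribution onto *surviving* chords happens only where chords share
nodes. Insertions disconnected from every papillary tip by a rupture are
unloaded and their chords reported slack.

Group forces (`group_force()`) sum tension vectors over the
origin-adjacent segment of every chord in a group — the papillary end, the
natural place to measure the pull on the muscle tip; whether the
leaflet-end convention was meant instead is ambiguous in the source
material, and this choice is deliberate and documented.
`pm_force_distribution()` normalises scalar tensions per papillary muscle;
rows sum to 100 by construction and the suite checks this to 0.1.

# Mitral regurgitation quantification

Sign conventions: forward flow positive for both valves; volumes in ml,
time in s, all integrals trapezoidal. The systolic window runs from the
first positive aortic-flow sample until aortic flow returns to zero, unless
explicit markers are supplied.

The mitral regurgitant volume is the integral of negative transmitral flow
over systole, split at the *control* valve's closure time — the first
upward zero-crossing of the control mitral flow after the onset of negative
systolic flow, located by linear interpolation. Retrograde volume before
that time is **closing volume** (blood displaced while the leaflets close),
after it **leakage volume** (true incompetence). Using the control
crossover for diseased records keeps the split comparable across
scenarios; a fixed `t_close` is accepted when no control exists. The split
inserts `t_close` into the quadrature grid so closing + leakage equals the
total retrograde systolic volume exactly.

Derived quantities: $RV_{MV}$ = closing + leakage; $LVSV = SV_{AV} +
RV_{MV}$; regurgitant fraction $RF = 100\,RV_{MV}/LVSV$. Severity grading
uses mild < 30 %, moderate 30–50 %, severe > 50 % — the unique simple
thresholds consistent with all eight severity labels of the reference
benchmark — plus the binary guideline category (severe above 50 %,
progressive otherwise).

```{r replay}
replay_reference_table()[, c("scenario", "rv_mv_ml", "rf_pct", "grade")]
```

The reference table (`reference_hemodynamics()`) carries the component
volumes of a published patient-specific FSI benchmark; one of its columns
(`total_P2P3`) is internally inconsistent at the second decimal
(components sum to 47.29 ml against a printed 47.19 ml), so the package
trusts components and the tests treat that column loosely.

# PV-loop energetics

Stroke work (SW) is the shoelace area of the closed PV loop, converted at
1 mmHg·ml = 1.33322 × 10$^{-4}$ J; clockwise loops are sign-corrected with
a warning. Forward stroke work (fSW) is the systolic time integral of
forward aortic flow times aortic pressure — the work actually delivered to
the circulation. Potential energy (PE) is the classical triangular area
under the linear end-systolic pressure–volume relation,
$\tfrac12 p_{es}(V_{es} - V_0)$; no formula for PE is fixed by the source
material, and the intercept $V_0$ is unidentifiable from the published
data, so it is a configurable parameter (default 0 ml) and absolute
efficiencies from this package are not comparable to the benchmark's
printed efficiencies — only their monotone decline with severity is. The
end-systolic point is the loop sample maximising $P/(V - V_0)$, overridable
by index. Efficiency is $100\,fSW/PVA$ with $PVA = PE + SW$; the source
material once writes the denominator as "PLA", which this package reads as
PVA, the only definition consistent with the accompanying
$PVA = PE + SW$ exposition.

# Synthetic data generator

The generator emulates, with analytic pulse shapes, the waveform features
that the analyses consume; printed scalars anchor its defaults (75 bpm,
0.8 s cycle, 414 ml/s peak aortic flow, 58.22 ml forward stroke volume,
4.27 ml aortic backflow, 8.65 ml closing volume, 20 mmHg atrial pressure,
80/120 mmHg aortic pressure, EDV 113 ml / ESV 47 ml). Waveform figures
were *not* digitized; all shapes are invented:

* **aortic flow**: a $\sin^2$ ejection pulse whose duration
  $2\,SV_{AV}/\hat q$ makes the integral exactly the target stroke volume,
  plus a small negative $\sin^2$ backflow pulse at valve closure;
* **mitral systole**: a negative $\sin^2$ closing spike of configurable
  volume placed just inside the ejection window (so re-detecting the
  systolic window from aortic flow captures it fully), a 0.15 ml positive
  rebound that gives the control record its mid-systolic upward crossing
  (the feature the closure-time detector keys on), and a ramped leak
  plateau at `leak_rate` ml/s — the severity knob — whose injected volume
  has the closed form `rate × (window − ramp)`;
* **mitral diastole**: E and A $\sin^2$ pulses with configurable peak
  ratio, scaled so diastolic inflow equals systolic output
  ($SV_{AV} + RV_{MV}$), emulating periodic steady state (LV volume then
  drifts by the small aortic backflow volume per cycle, which no analysis
  consumes);
* **pressures**: 80–120 mmHg aortic profile; constant 20 mmHg atrial
  pressure, or a half-sine systolic V-wave of configurable peak for
  regurgitant conditions (its amplitude is a free parameter — no published
  value constrains it);
* **noise**: optional seeded Gaussian noise on both flow channels, default
  zero so analysis runs are deterministic; the noise stream swaps the
  session RNG state in and out, so generation never perturbs user code.

Default `dt` is 1 ms and a record must contain at least 200 samples per
cycle. `gen_severity_suite()` holds the ejection duration at the control
value across a severity sweep, so one closure time applies to every
record; `gen_reference_suite()` drives it with the benchmark component
volumes, giving an end-to-end replay of the published hemodynamic table
through waveform synthesis and re-analysis. The closing-spike volume is a
knob, not a prediction: the mechanistic link between rupture extent and
closing volume requires leaflet dynamics the generator cannot emulate.

What passing recovery tests do show: the quadrature, windowing and
splitting logic recover injected volumes to well under 1 % on waveforms
with realistic time scales. What they do not show: robustness to
measurement noise spectra, beat-to-beat variability, or waveform shapes
outside the generator's family.

# Numerical choices and problem sizes

* Trapezoidal quadrature throughout; halving `dt` moves volumes by
  < 0.2 %.
* Truss tolerance $10^{-8}$ relative, regularisation $10^{-7}$, load
  stepping ×10, displacement cap 0.5 × mean element length — chosen for
  robustness on slack-prone cable networks, none dictated by the source
  material.
* The default network has ~450 nodes and ~430 segments; a full solve takes
  a few seconds, and the test suite and verification scripts use one
  control solve plus closed-form miniatures (single chord, symmetric V,
  parallel pair) rather than repeated full-network sweeps.
* Finite-difference verification uses 100 random states; waveform recovery
  uses 20 seeded configurations.

# Known limitations

* The tributary-area load model cannot reproduce FSI chordae tensions or
  their redistribution after rupture; only the aggregation arithmetic and
  equilibrium properties are validated.
* Absolute LV efficiency depends on the unidentifiable $V_0$; only trends
  are meaningful.
* The idealized annulus/scallop geometry preserves topology and group
  labels, not patient anatomy; lengths and angles are plausible, not
  measured.
* Single-cycle records only; no atrial mechanics, no jet quantities, no
  repair modelling.
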