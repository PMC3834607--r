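---
title: "Methods: lower-extremity inverse dynamics, static optimization and knee cocontraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lower-extremity inverse dynamics, static optimization and knee cocontraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, numerical
choices, and the synthetic data it is validated on. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The scientific question

In medial knee osteoarthritis (OA), gait changes are expected in two
linked quantities that cannot be measured non-invasively: the forces in the
individual knee-crossing muscles and the bone-on-bone contact force at the
tibiofemoral joint. The package estimates both from what a gait laboratory
*can* measure — marker trajectories and ground reactions — and summarizes
antagonist cocontraction through two ratios over the four knee extensors
(VINT, VLAT, VMED, RF) and eight knee flexors (SM, ST, BFLH, BFSH, GASM,
GASL, SAR, GRA):

* `EFAR = (A_VINT + A_VLAT + A_VMED + A_RF) / (A_SM + ... + A_GRA)`, from
  activations `A_i = F_i / (sigma_i PCSA_i)`,
* `EFTR`, the same ratio built from the magnitudes of each muscle's knee
  flexion-axis torque contribution.

## Model

**Segments and scaling.** Six limb segments (thigh, shank, foot, both
sides) hang off a pelvis base; each joint contributes three rotational DOF
(18 total). Segment masses are Winter-style fractions of body mass (thigh
0.100, shank 0.0465, foot 0.0145; the pelvis row carries the remaining
0.678 so the model mass always equals the subject mass). COM positions and
radii of gyration are fractions of segment length; every local coordinate
scales linearly with the subject-to-reference segment-length ratio (the
pelvis scales with inter-ASIS width). The tables live in
`inst/extdata/model_parameters.yaml` — one editable file — and are the
package's own synthesis of the standard anthropometric and lower-limb
muscle literature, not a copy of any single published table.

**Muscles.** 26 musculotendon units per limb with straight-line paths,
with one deliberate exception: the four quadriceps route through a
patellar via point fixed on the distal thigh (4.5–5 cm anterior of the
knee center). Without it, the straight femur-to-tibial-tuberosity line
passes through the knee center at roughly 35 degrees of flexion and the
extensor moment arm collapses to millimeters — a well-known artifact of
line-of-sight quadriceps models — making swing-phase knee extension
demands unmeetable. The via point keeps the extensor arm at 3.5–4.5 cm
across the flexion range while every other muscle remains a single line.
At each joint, the polyline segment that spans the joint defines the unit
force direction `tau_i` on the distal bone and the moment `r_i x tau_i`;
a test verifies these geometric arms against tendon-excursion derivatives
(`dL/dq`) to 1e-6 m.

**Strength.** Maximum isometric force is `sigma * PCSA` with a uniform
default `sigma` = 61 N/cm², overridable per muscle group and scalable by
an age factor. PCSA scales with subject size as mass divided by the
limb-length scale (muscle volume proportional to body mass): joint moment
demands grow with body mass, and a strength model that ignored size would
make heavy subjects artificially weak relative to their own loads.

## Pipeline

**Poses.** Marker clusters are fit by least-squares rigid transforms
(Kabsch SVD). The pelvis uses its four markers; distal segments use their
two anatomical markers plus the shared joint center reconstructed from the
proximal segment (hip from Bell-style fractions of inter-ASIS width, knee
and ankle as condyle/malleolus midpoints), which gives each cluster three
well-separated points. Collinear clusters are rejected, gap frames are
flagged (an explicit `fill_marker_gaps()` exists for gaps of up to five
frames; nothing is interpolated silently).

**Angles, rates, events, normalization.** Joint angles decompose the
parent-to-child rotation in the intrinsic Z–X–Y (flexion, adduction,
internal rotation) sequence with side-aware signs; angular velocity is the
axial vector of `Rdot R'`; all derivatives are second-order central
differences (exact for quadratics, with one-sided second-order endpoint
stencils). Heel strike and toe off are threshold crossings of the vertical
ground reaction (20 N, 20 ms debounce). Every series is linearly
interpolated onto 100 evenly spaced cycle points; multiple cycles are
averaged pointwise *after* all per-cycle computation.

**Filtering.** Zero-lag Butterworth (2nd order forward-backward, effective
4th order) with odd-reflection padding; 6 Hz for markers, 20 Hz for force
plates before 10:1 decimation onto the marker clock. Both cutoffs are
configuration keys, chosen as the field's customary values.

**Net loads.** Bottom-up Newton–Euler recursion, foot to thigh, with the
ground reaction applied at the center of pressure and the free moment
channel included. Loads are reported at joint centers in the lab frame
with anatomical-frame views derived on demand. The recursion is verified
against a whole-limb equilibrium oracle, a swinging-segment pendulum
closed form (1% at 100 Hz), and lab-frame origin invariance.

**Static optimization.** At each cycle point, per limb:

minimize `sum_i (F_i / A_i)^3` subject to
`sum_i F_i (r_i x tau_i) = M_e` on the constrained DOF and
`0 <= F_i <= sigma_i A_i`.

The constrained set defaults to six of the nine rotational DOF: all three
at the hip, knee flexion and knee ad/abduction, and ankle
plantar/dorsiflexion. The 26-muscle set contains no ankle evertors and no
dedicated knee or ankle axial rotators, so those three moments are
structurally under-actuated; feasibility analysis over whole gait cycles
shows irreducible violations of 2–30 N·m when they are constrained and
exact feasibility when they are not. Treating them as passively borne by
joint structures is standard static-optimization practice; the knee
frontal DOF — the constraint that couples the adduction moment into
muscle recruitment and hence into the mediolateral contact force — is
always retained. The set is configurable
(`pipeline_config(constrained_dofs = )`).

The program is smooth and strictly convex, so the KKT system
characterizes the unique optimum: with multipliers `lambda` and
`s = R' lambda`, `F_i(lambda) = clip(A_i^{3/2} sqrt(max(s_i, 0)/3), 0,
fmax_i)`. The solver runs a damped semismooth Newton iteration on the
constraint residual `M_e - R F(lambda)` (6×6 linear solves), warm-started
from the exponent-2 problem (whose multipliers solve a linear system) and
from the previous cycle point; a BFGS ascent of the concave dual is the
fallback. Points whose demanded moment exceeds total muscle capacity are
flagged and resolved by bounded least squares on the residual — bounds
are never relaxed. Tolerances: constraint `1e-8 * (1 + ||M_e||)`,
verified stationarity reported per point.

**Contact force and metrics.** `F_j = F_e - sum_i F_i tau_i` over the
twelve knee-crossing muscles, decomposed in the shank frame: axial
(positive tensile, stance values compressive/negative), mediolateral
(positive medial), anteroposterior (positive posterior). The tabulated
peaks are the compressive magnitude, the peak *medial* component (the
compartment of interest in medial OA; in this model the medial peak is
what responds to the load-line shift while the lateral extremum is
insensitive), and the signed AP extremum. Summary EFAR/EFTR are ratios of
cycle means — pointwise ratios explode during near-zero flexor phases, so
the pointwise series is exported separately with sub-floor denominators
flagged. Group comparison uses Welch's t test by default (pooled-variance
optional) with significance at 0.05 and no multiplicity correction.

## Synthetic gait generator

The generator emulates one study design: two groups walking at
self-selected speed, 37 markers at 100 Hz, per-foot force plates at
1000 Hz. Joint-angle waveforms are 4-harmonic Fourier templates fitted to
normative-shaped control curves; forward kinematics places the markers
(isotropic Gaussian noise, default SD 1 mm); the vertical ground reaction
is a double-hump profile through fixed knots (peaks 1.10/1.05 BW, valley
0.72 BW) whose stance impulse matches body weight times step time within
about 1%; braking/propulsion and mediolateral shear are low-amplitude
half-sine shapes; the center of pressure progresses heel to toe.

Cohorts draw subject mass and stature from group-specific Gaussians
(normal: 58.5 ± 10.5 kg, 1.64 ± 0.054 m; OA-like: 73.1 ± 13.4 kg,
1.60 ± 0.080 m), cadence from N(110, 5) steps/min, and small per-subject
waveform idiosyncrasies (DC offsets SD 1.5 degrees, amplitude scale SD
5%). All randomness flows from one seed; identical seeds give
bit-identical trials.

**The OA-like mode** is driven by a single severity knob, the load-line
lever offset in meters (default 0.04). It moves the center of pressure
*medially* — the direction that raises the external knee adduction moment,
as a varus-aligned medial-OA limb does — and slaves two sagittal
signatures of OA gait to the same knob: a knee flexion contracture of
`150 * severity` degrees and a dynamic flexion range scaled by
`1 - 3.75 * severity`. The contracture matters: the load-line shift alone
recruits small-PCSA lateral flexors (their activation rises faster than
the extensors'), while the contracture raises stance-phase quadriceps
demand throughout, which is what produces the extensor-dominated
cocontraction pattern cohort studies report. At severity 0 the two groups
are drawn from identical distributions, so the null comparison is exactly
calibrated.

**What passing tests do and do not show.** The generator's kinematics are
prescribed and its ground reaction is parametric, so its trials are
impulse-consistent but not instantaneously dynamically consistent, and
foot-ground clearance is approximate (templates that sink markers more
than 3 cm are rejected). Pipeline results on synthetic cohorts therefore
validate the *computational chain* — geometry, recursion, optimization,
metrics, statistics — under controlled conditions, not the physiology of
real OA gait. The exact oracle for the optimizer is not the gait data but
the consistency fixture: muscle forces constructed from the KKT
stationarity form with chosen multipliers, whose moments make them the
unique optimum; the solver recovers them to better than 1e-5 relative.

## Problem sizes and reproducibility

The shipped analyses use one gait cycle per subject, 100 cycle points, 21
subjects per cohort (10 normal, 11 OA-like), and 20 seeded cohort
replications for the directional property checks; these sizes make every
result reproducible on a laptop in minutes while leaving the estimators'
behavior unchanged (cycle averaging and per-point solving are independent
of how many cycles or subjects are processed). Every random draw descends
from an explicit integer seed, and the pipeline itself is deterministic:
rerunning any stage on the same inputs is bit-identical.

## Known limitations

* Single-resultant knee contact (no medial/lateral condyle split), rigid
  tendons, no activation dynamics, no wrapping surfaces beyond the
  patellar via point.
* Knee/ankle axial rotation and subtalar moments are not muscularly
  balanced (see the constrained-DOF discussion); hip axial rotation is.
* Compressive contact peaks on the synthetic cohorts run 4–6 BW, above
  the 2–3 BW range instrumented implants report; a single-line,
  single-resultant model with frontal-plane constraints overestimates
  the stabilizing muscle load, and the synthetic ground reactions are
  not subject-optimized. Group *contrasts* are the quantity of interest.
* The TRC-style text format and per-plate CSV are the only interchange
  formats; vendor binary formats are out of scope.
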