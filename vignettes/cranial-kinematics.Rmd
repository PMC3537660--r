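---
title: "Methods: landmark-based cranial kinematics of feeding and climbing gobies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark-based cranial kinematics of feeding and climbing gobies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gobykin)
```

## The scientific problem

Waterfall-climbing gobies of the genus *Sicyopterus* use their mouth for two
very different jobs: scraping diatoms off the substrate during feeding, and
cyclically attaching an oral sucker to rock while "inching" up waterfalls.
Both behaviors are cyclic protrusion–retraction movements of the same cranial
elements, which raises a comparative question: are the two motor patterns
variants of one kinematic program, or distinct programs? The quantitative
handle on that question is (i) per-cycle peak values of cranial kinematic
variables, compared across groups with nonparametric rank tests, and (ii) the
overall *shape* of each variable's trajectory through the cycle, compared as
the angle between mean kinematic-profile vectors.

`gobykin` implements that full analysis as a reusable, tested pipeline:
landmark input and registration, eight kinematic variables, percent-cycle
normalization, the two comparison layers, and a synthetic cyclic-motion
generator that makes every stage testable with known ground truth.

## Data model and registration

Input data are digitized 2-D landmark coordinates from two synchronized
high-speed video views: 14 ventral-view landmarks (ids 1–14) and 9
lateral-view landmarks (ids 15–23). A behavioral cycle starts with the first
forward movement of the premaxilla and ends when its rearward movement is
complete; a digitized trial spans one cycle at a fixed frame rate (500 Hz for
feeding, 200 Hz for climbing in the default regimes).

Because the digitizing software imposes no axis convention, the package fixes
one: ventral view x = mediolateral (fish's right positive), y =
anteroposterior (anterior positive); lateral view x = anteroposterior
(anterior positive), y = dorsoventral (dorsal positive). Counterclockwise
rotations are positive, and every variable is signed so that *positive means
the named motion*.

Every frame is translated so that the midpoint of the pectoral-fin base
landmarks (12/13 ventrally, 22/23 laterally) sits at the origin. This
"stationary point" is part of the hyoid and mandible variable definitions; we
extend it to *all* displacement variables because climbing trials contain
whole-body translation up the substrate that would otherwise contaminate
"relative to start" measures. Registration is idempotent, invariant under
rigid translation of the raw data, and removes whole-body advance exactly
(both properties are tested).

Registration removes translation only. Whether lateral-view angles should
additionally be corrected for the inclination of the climbing substrate is
not resolvable from landmark data alone; the change-from-start formulation of
the angle variables sidesteps the choice of an absolute reference direction,
at the cost of leaving any within-cycle body-axis rotation in the signal.
This is a documented limitation.

Interior gaps in a landmark's trajectory (at most 3 frames by default) are
filled by linear interpolation and logged; longer gaps, or gaps touching the
cycle boundary, invalidate the trial rather than being guessed at. Degenerate
geometry (coincident or collinear mouth landmarks) likewise raises an error
for the cycle instead of being skipped silently, because a silently dropped
frame would corrupt the 101-point profiles downstream.

## The eight kinematic variables

Angles are in degrees; lengths are normalized by total body length (BL),
areas by BL². Point numbers refer to the 23-landmark scheme; M is the
pectoral-fin midpoint (the origin after registration).

| Variable | Definition |
|---|---|
| Cranial elevation angle | rotation of vector 18→20 relative to frame 0 (lateral) |
| Premaxillary protrusion angle | rotation of vector 15→18 relative to frame 0 (lateral) |
| Premaxillary protrusion length | 2-D displacement of point 15 from frame 0 (registered lateral) |
| Hyoid retraction angle | angle at point 8 between 8→M and 8→11 (ventral, unsigned) |
| Hyoid retraction length | shortening of distance(8, M) from frame 0 |
| Mandibular retraction length | shortening of distance(3, M) from frame 0 |
| Opercular expansion length | absolute distance between points 10 and 11 |
| Oral sucker area | geometric model on points 1, 3, 4, 6 (below) |

Design choices worth making explicit:

* **Protrusion length is a 2-D magnitude**, not only the anteroposterior
  component, because the premaxilla moves both forward and ventrally and the
  variable is defined as a distance.
* **Hyoid retraction angle is the raw inter-vector angle**, not a
  change-from-start score, mirroring the variable's definition, which —
  unlike the other angle variables — does not reference the start of the
  cycle.
* **Opercular expansion is an absolute width**, not an excursion: its
  published feeding maxima (≈0.17 BL) are far larger than any plausible
  excursion, so the variable must be the inter-opercular distance itself.
* **Hyoid and mandibular retraction are both signed so that motion toward M
  is positive.** A literal reading of one formulation would give the hyoid
  the opposite sign from the mandible for the same motion; we apply the
  package-wide rule that positive always means the named motion.

### The oral-sucker-area model

The ventral mouth outline is reduced to four landmarks — A (point 1), B
(point 3), C (point 4), D (point 6) — plus the computed chord midpoint E of
B and C, and θ, the angle at A between vectors AB and AC. The modeled area is
the sum of three shapes, with bilateral symmetry accounting for the left
side:

* **X** — circular sector at A of angle θ and radius |AB| (the anterior lip):
  `θ·|AB|²/2`;
* **Y** — triangle A-B-C: `|AB × AC|/2`;
* **Z** — triangle B-D-C (the mandibular bulge beyond the chord BC):
  `|(D−B) × (C−B)|/2`.

The formulas live in a single function locked by golden-value regression
tests, and the model is cross-checked against a brute-force polygonal
integration of the same three shapes (fine fan polygon for the sector,
shoelace for the triangles) to 0.5% on randomized valid mouth
configurations. Exact quadratic scaling under coordinate doubling and O(ε)
continuity in every landmark are tested properties.

## Percent-cycle normalization

Each variable's per-frame trace is smoothed with a **quintic smoothing
spline**: a degree-5 B-spline basis with knots at the data sites and a
third-derivative roughness penalty, fitted by penalized least squares
through a single augmented QR solve. The penalty weight is chosen per trial
per variable by **generalized cross-validation** (GCV), since the historical
smoothing setting behind this analysis style is not recorded anywhere; the
selected value is written to a smoothing log for reproducibility. Setting
the smoothing parameter to zero gives exact interpolation; because the
penalty annihilates cubics, constant through cubic trends are reproduced
essentially exactly at any smoothing level.

The fitted spline is evaluated at 101 evenly spaced increments spanning the
closed cycle (0%, 1%, …, 100% — both endpoints included), which normalizes
cycles of any duration onto a common axis: a 0.141 s feeding cycle sampled
at 500 Hz and a 0.313 s climbing cycle sampled at 200 Hz with the same
underlying shape yield the same 101-point profile to within spline
tolerance (tested at 10⁻³ of amplitude). Profiles are aggregated pointwise
into mean ± s.e.m. (sample SD / √n) per group, with the cycle as the
sampling unit — the same pseudoreplication caveat as any per-cycle design;
per-individual aggregation is possible by grouping on `individual_id`.

Per-cycle **peak values** are taken from the smoothed, resampled profile
(maximum of the 101 values); raw per-frame maxima are also available as a
sensitivity check (`raw_cycle_peaks()`), and agree closely for clean cycles.

## Group comparison

Peaks are compared with the **Mann–Whitney U** test for two groups (exact by
enumeration when `n_a + n_b ≤ 12` with no ties, otherwise the normal
approximation with tie-corrected variance and continuity correction) and
with the **Kruskal–Wallis** test for three or more. Both are thin wrappers
over the standard R implementations, with the exact/approximate switch fixed
by the rule above; an independent from-scratch enumeration of rank
configurations serves as the test-suite oracle. Two-sided p-values
throughout, α = 0.05, no multiple-testing correction — each variable is
reported on its own.

Profile shape is compared with the **divergence angle**: the angle between
two 101-dimensional mean-profile vectors, `acos(u·v / (‖u‖‖v‖))`, computed
on the *raw* (uncentered, unscaled) mean profiles. Uncentered vectors are
the natural reading of vectors "generated from the 101 mean values", and
they make the angle amplitude-insensitive for proportional profiles — two
groups with the same shape but different amplitude diverge by ≈0°, which is
exactly the behavior that lets small angles coexist with significantly
different maxima. (Whether the original analysis centered its vectors is
not stated anywhere we can check; uncentered is this package's documented
choice.) Numerically the angle is computed from chord lengths of the unit
vectors rather than a bare `acos`, which keeps full precision near 0°.
Divergence angles are treated descriptively — no permutation test — matching
how such angles are conventionally reported.

## The synthetic-data generator

The generator exists so that every pipeline stage can be validated without
any archival video data, and so that parameter recovery can be quantified.
It is *not* a tuning dial: its defaults encode the study conditions —
feeding cycles of 0.141 s at 500 Hz (71 frames), climbing cycles of 0.313 s
at 200 Hz (64 frames), amplitudes set to the published mean maxima for each
behavior, and a study design of 96 feeding cycles from 4 individuals and 36
climbing cycles from 3 individuals.

A virtual head is built from a resting geometry: the premaxilla (point 15,
with point 1 ventrally) protrudes along a half-sine rise-and-return pulse;
the mandible (points 3/6/7) and hyoid (point 8) retract toward the pectoral
midpoint with a phase lag (default 0.25 of the cycle — retraction follows
peak protrusion, as described for both behaviors); the opercula widen with
the same lagged pulse; reference landmarks are stationary in the body frame;
climbing adds a uniform whole-body advance; and isotropic Gaussian
digitizing noise (default 0.01 cm, sub-pixel for these image scales) is
added last.

Geometric couplings worth knowing:

* Premaxillary protrusion *length* and *angle* are tied through the radius
  of rotation of point 15 about point 18, `r = L·BL / (2 sin(A/2))`, so both
  peak amplitudes are met exactly while the length trace follows
  `2r·sin(φ(t)/2)` — the exact closed form is what the generator emits as
  ground truth.
* Hyoid retraction angle and oral sucker area have no free amplitude: they
  are emergent from the constructed geometry (the mouth template is scaled
  so the area model hits the requested resting area exactly). Their ground
  truth is computed in closed form inside the generator — the same geometry
  the variable definitions measure, written as an independent code path from
  the kinematics module.
* With zero noise, the pipeline recovers every generated trace to machine
  precision (tested at 10⁻⁹), and every amplitude within 1% after smoothing
  and resampling.

Individual-level variation is a lognormal multiplier on the motion
amplitudes (default CV 10%) and cycle durations are jittered lognormally
(default CV 5%); no within-individual variance components are reported
anywhere for this system, so these are sensitivity-analysis placeholders,
not estimates, and both are configurable per group.

What the generator does **not** emulate: 3-D projective geometry (each view
is an independent 2-D plane), substrate-reaction mechanics, asymmetric
left–right motion, autocorrelated digitizing error, or tracking dropout
bursts. Passing the recovery tests therefore demonstrates correctness of the
pipeline's mathematics on data satisfying its assumptions, not robustness to
every failure mode of real video digitizing.

## Problem sizes and numerical choices

The test suite and the acceptance script run synthetic studies at the scale
of the original design where that matters (96 + 36 cycles for the
constructed-shape recovery; 50 cycles per group for the null-design check)
and smaller, faster studies where only structure is being exercised. The
spline fit requires ≥ 8 frames per cycle; GCV minimizes over a wide
log-spaced penalty range; evaluation outside the fitted time span is an
error rather than an extrapolation. Ties in rank tests use midranks with
tie-corrected variance; a fully degenerate comparison (all values identical)
returns p = 1 with a classed warning.

## Worked example

```{r example, eval = FALSE}
# simulate the default two-behavior study, then analyze it
sim_dir <- tempfile(); out_dir <- tempfile()
cmd_simulate(sim_dir, seed = 1)
res <- cmd_analyze(file.path(sim_dir, "landmarks.csv"), out_dir, seed = 1)

res$report$summary_table
#  mean divergence angle across the eight variables, its s.e.m.,
#  and the counts of variables below 5 and 10 degrees

# published-table summaries
ds <- divergence_summary(reference_feeding_climbing()$divergence_angle_deg)
round(c(ds$mean, ds$sem), 1)   # 9.0  2.4
```

## Known limitations

* Lateral-view angles are not corrected for substrate inclination (see
  above); residual body rotation within a cycle is unquantified.
* The published group statistics for the two suction-feeding outgroup
  species derive from a prior study's video data and enter this package
  only as printed summary tables; the package can compare such precomputed
  profile sets (`cmd_compare()`) but cannot re-derive them.
* The cycle is the sampling unit for all tests; with 3–4 individuals per
  group, individual and group effects are partially confounded, as in any
  design of this shape.
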