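---
title: "Methods: four-dimensional elbow simulation with elbow4d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: four-dimensional elbow simulation with elbow4d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elbow4d)
```

## The problem

Debridement arthroplasty for primary degenerative elbow osteoarthritis
removes the marginal osteophytes that abut at the extremes of motion. The
surgeon's difficulty is localizing, before opening the joint, exactly which
bony prominences impinge and at which flexion angles. elbow4d implements a
"four-dimensional" (3D + time) simulation built from a *single* CT position:
a hinge axis is estimated from the distal humerus, the forearm model is
rotated about it through the flexion-extension arc, and bony overlap is
quantified and localized at each angle.

## The two-rings axis

Although the in-vivo flexion-extension axis migrates slightly through the
arc, its mean is close to the line joining the centers of the trochlea and
the capitellum. The two-rings method estimates that line from six clicks:

1. Three points are plotted on the trochlea and three on the capitellum.
2. A circle ("ring") is drawn through each triple — `circumcircle3()`
   solves the unique circle through three non-collinear 3D points from the
   two linear equidistance conditions in the points' plane.
3. The axis is the line through the two ring centers, oriented from the
   trochlea (medial) toward the capitellum (lateral); `two_rings()` also
   reports ring radii, the inter-center distance and each ring normal's
   angle to the axis as plausibility diagnostics. Centers closer than 1 mm
   are rejected as an unstable axis.

`fit_ring()` generalizes to more than three points (total-least-squares
plane, then a Kasa circle fit in that plane) so reliability experiments can
use richer landmark sets, but the published method's default is the exact
3-point circumcircle.

Flexion is a right-handed rotation about the axis direction; a `flip` flag
(CLI `--side left`) covers the contralateral convention. Landmarks are used
as given — the operator clicked on a rendered surface — with an optional
snap-to-nearest-vertex mode for hand-edited files.

## Kinematics

The forearm (ulna + radius, one rigid body; pronosupination and
varus-valgus laxity are out of scope) is posed by an axis-angle rotation
about the hinge (`rotation_about_axis()`, Rodrigues form). Every pose is
built directly from the reference pose at its absolute angle — poses are
never chained — so orthonormality cannot drift over long sweeps, and the
enclosed volume of the posed mesh is conserved to better than 1e-6
relative.

The flexion angle of the scanned reference pose cannot be recovered from
the mesh itself; it must be supplied (`reference_angle_deg`) from the
clinical extension measurement. The phantom's reference pose is defined at
0° (full extension) by construction.

## Impingement as voxel overlap

Exact mesh booleans are brittle for the near-tangent contacts of articular
surfaces. elbow4d instead voxelizes both bones on a common cubic grid
covering the intersection of their bounding boxes (padded one cell) and
counts cells whose centers lie inside both meshes:

* point containment is parity ray casting along a fixed, jittered
  direction, with on-surface points classified inside;
* the volume estimate is exactly `cells x voxel_size^3`, and its error is
  bounded by one voxel layer over the contact area;
* faces whose centroid lies inside the other bone are labeled impinging and
  exported red (RGB 255,0,0) in PLY frames.

Defaults: `voxel_size` 0.5 mm (sub-millimetre CT scale at desk cost; the
analytic checks below use 0.2–0.25 mm), `contact_threshold` 0 mm³, sweep
step 1° — already the precision of clinical goniometry, so no root
refinement is attempted on the sampled profile. `flexion_sweep()` defines
the impingement-free arc as the longest contiguous run of sub-threshold
angles; its end points are the first-contact angles, reported as missing
when the free run reaches the swept limit.

Numerical care in the voxelizer: voxel centers are offset by ~1e-4 cell in
each dimension so lattice-aligned facets are never hit exactly, and the 2D
point-in-triangle test uses the half-open crossing rule, which assigns a
column lying exactly on a shared edge to exactly one of the two adjacent
triangles — column parity stays consistent on watertight input.

## The phantom: analytic ground truth

`make_phantom()` builds an idealized hinge joint about the x-axis: a
trochlear cylinder (default radius 10 mm), a capitellar sphere (8 mm) 40 mm
away, a humeral shaft box, and a forearm arm whose near facet is the plane
at `trochlea_radius + clearance` (default 0.5 mm) from the axis. Two
deliberate idealizations:

* the forearm's articular side is a planar facet rather than a concave cup,
  so osteophyte contact angles stay exactly closed-form;
* osteophytes are spheres standing 0.2 mm off the trochlear surface, so
  every component is a disjoint simple closed surface and parity
  containment plus divergence-theorem volumes remain exact. They move
  rigidly with the humerus; forearm-side bosses are not supported because a
  boss at fixed radius from a coaxial hinge never changes its clearance
  under rotation.

A boss of radius $s$ standing off by $g$ at angular station $\phi$ has
center radius $\rho = r_t + g + s$ and touches the facet plane over
$\phi \pm \alpha$ with $\alpha = \arccos((r_t + c - s)/\rho)$, $c$ the
clearance. `osteophyte_for_contact()` inverts this so a phantom can be
designed to first contact at, say, 120°; the generator's closed form is
cross-checked in the tests against a per-vertex analytic oracle on the
built mesh (agreement within 0.1°, limited only by icosphere faceting) and
recovered end-to-end by the 1° voxel sweep within one step.

`sample_landmarks()` draws three seeded ring angles per articular surface
and adds isotropic Gaussian noise; the same seed reuses the same angles and
unit noise vectors across noise levels, so noise studies are paired by
seed. The minimum angular separation defaults to 20° (just enough to
exclude near-collinear triples). A finding worth flagging: triples
clustered near that floor amplify landmark noise by an order of magnitude
into circumcenter error — the 3-point method's main fragility — so studies
emulating deliberate operator spreading should set `min_separation_deg`
near 60°, as the reliability simulation below does.

What the phantom does *not* emulate: real articular congruence, cortical
texture, segmentation artifacts, or operator landmarking bias toward
recognizable anatomy. Passing phantom tests validates the geometry and the
pipeline, not the clinical accuracy of axis identification on pathological
bone.

## Statistics

Reliability of duplicate overlap-volume measurements uses the
single-measure, absolute-agreement intraclass correlations: one-way random
ICC(1,1) for intraobserver (test-retest) and two-way random ICC(2,1) for
interobserver agreement, computed from the ANOVA mean squares assembled
from definitions. The named models do not pin down single-vs-average or
consistency-vs-agreement; single-measure absolute agreement is the standard
reading for two observers each measuring twice. 95% confidence intervals
use the F-distribution forms (Satterthwaite degrees of freedom for
ICC(2,1)); both estimates and intervals are verified in the tests against
an independent implementation. Interpretation follows the conventional
thresholds: above 0.75 excellent, 0.4–0.75 fair to good, below 0.4 poor.

Cohort outcomes are summarized as mean (±SD) with half-away-from-zero
rounding for presentation. "Student t-test" is underspecified for this
design, so the data structure decides: paired t for within-patient pre/post
change, Welch for open-vs-arthroscopic group contrasts. Range-of-motion
records must satisfy arc = flexion + signed extension (extension deficit
is negative); the reader rejects tables that violate it.

## Study conditions of the shipped analyses

The acceptance script (`scripts/acceptance.R`) recomputes, at modest desk
scale:

* cohort means from the bundled 11-patient ROM table;
* axis-fit exactness on noiseless phantom landmarks and the circumcircle
  equidistance property over 100 random triples;
* two analytic overlap recoveries — the equal-sphere lens (R = d = 10 mm,
  closed form $5000\pi/12 \approx 1309$ mm³, voxel 0.25 mm, subdivision-4
  icospheres whose faceting deficit is ~0.3%) and half-overlapped unit
  cubes at voxel 0.05 mm;
* the end-to-end 105–135° sweep at 1°/0.2 mm recovering the designed 120°
  contact;
* a simulated reliability study: 11 phantoms with 2–4 mm osteophytes at
  stations 128–136°, clearance 1 mm (a degenerate joint is not tightly
  congruent), two observers x two sessions relandmarking with 0.2 mm noise
  and 60° spreading, rating the 140° overlap at voxel 0.25 mm. Between-
  patient osteophyte variation dominates observer noise, so the simulated
  ICCs land in the excellent band (~0.99); they demonstrate the workflow
  rather than reproduce any clinical value;
* the landmark-noise curve: median axis angular error over 200 paired
  seeds at sigma 0.25/0.5/1.0 mm, which is monotone in sigma.

## Known limitations

* The axis is a fixed line; physiologic axis migration through the arc is
  not modeled.
* Overlap semantics are a reconstruction: the original CAD software's
  volume computation is unspecified, so absolute volumes are comparable
  within this package only.
* Cartilage, soft-tissue constraint and resection planning are out of
  scope; the output localizes bone-on-bone abutment only.
* STL carries no units; coordinates are assumed millimetres (a
  `units_scale` override exists for nonstandard exports).
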