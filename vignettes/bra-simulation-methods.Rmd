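---
title: "Methods: biomechanical simulation and evaluation of bimaxillary rotation advancement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomechanical simulation and evaluation of bimaxillary rotation advancement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

Bimaxillary rotation advancement (BRA) treats obstructive sleep apnea (OSA)
by moving both jaws forward (and rotating them counter-clockwise in the
sagittal view), which mechanically widens the constricted pharyngeal
airway. The same bone movements also reshape the face. Planning therefore
has to trade off a functional target (airway cross sections, especially the
narrowest velopharyngeal section) against an esthetic one (facial
contours). `bramax` implements the computational core of such a planning
loop: given a jaw-displacement plan, it predicts the soft-tissue
deformation of face and airway with a finite-element model, and it
quantifies outcomes with the same morphometric and surface-distance
measures a clinical evaluation would use.

No patient imaging ships with the package. Every stage is instead
exercisable on a deterministic synthetic phantom (`make_head_phantom()`),
and the cohort statistics run on packaged planning tables.

## Soft-tissue model

Soft tissue is modeled as a piecewise isotropic, homogeneous, geometrically
nonlinear elastic continuum. The constitutive law is the generalized
Hookean relation applied to the Green–Lagrange strain
$\varepsilon = \tfrac12(F^\top F - I)$:

$$\sigma(\varepsilon) = \frac{E}{1+\nu}\Big(\varepsilon +
  \frac{\nu}{1-2\nu}\,\mathrm{tr}(\varepsilon)\, I\Big)
  \;=\; 2\mu\,\varepsilon + \lambda\,\mathrm{tr}(\varepsilon) I .$$

The stress of this law is taken work-conjugate to the Green–Lagrange
strain, i.e. it plays the role of the second Piola–Kirchhoff stress in a
total-Lagrangian formulation. That makes the model a St. Venant–Kirchhoff
hyperelastic material: a linear stress–strain relation on a finite-strain
measure. Pairing the same linear relation with a spatial (Cauchy) stress
instead would not define a well-posed hyperelastic energy; the St.V–K
reading reproduces the same formula verbatim and reduces to classical
linear elasticity in the small-strain limit. The practically important
property — and the reason a geometrically nonlinear model is needed at all
for centimeter-scale jaw movements — is frame indifference: rigid motions
produce exactly zero strain, which the test suite verifies as a
`1e-10` bound on the ratio of nonlinear to small-strain energy under rigid
boundary data.

Parameters, per material region:

* `E` — Young's modulus in Pa. Default 15 kPa for `soft_tissue`, a typical
  bulk stiffness for facial soft tissue. Because all boundary conditions
  are prescribed displacements (no loads), the *absolute* stiffness scale
  cancels from the predicted deformation of a homogeneous model; it
  matters only for relative stiffness between regions.
* `nu` — Poisson's ratio, default 0.45 (nearly incompressible, as is usual
  for hydrated tissue). The law is singular at `nu = 0.5`; the constructor
  enforces `-1 < nu < 0.5` strictly.

Bones (skull, jaw fragments) are rigid: bone-region elements are removed
from the elastic system and bone interfaces enter as Dirichlet data. Air
(airway lumen, nasal cavities) is void — no elements.

## Discretization and solver

* Element: 4-node linear tetrahedron with one-point quadrature (exact for
  constant-strain elements). Internal forces and the exact consistent
  tangent (material + geometric stiffness) are assembled in C++.
* Nonlinear solve: Newton–Raphson with proportional load stepping (default
  4 increments), a halving line search on residual increase, and an
  element-inversion guard. Convergence is a relative residual below
  `newton_tol` (default 1e-8) per step. The tangent is symmetric, so the
  reduced system is factorized with sparse Cholesky (CHOLMOD), falling
  back to sparse LU if positive definiteness is lost along the path. Four
  increments were chosen because the converged solution is
  increment-independent and Newton converges robustly at clinically
  realistic plan magnitudes (≤ 15 mm advancement on the phantom); the
  option remains user-settable for more extreme deformations.
* The patch test (affine boundary data reproduced to machine precision on
  unstructured meshes) and the finite-difference tangent check pin down
  the element implementation.

## Jaw plans and boundary conditions

A plan is (Mxi, Mxp, Mdp, CCW angle): maxillary impaction and protrusion,
mandibular protrusion (all in cm, matching clinical planning tables), and
a counter-clockwise rotation about the patient-left (+x) axis. Impaction
is stored unsigned and applied superiorly (+z); protrusion is anterior
(+y). The maxilla rotates about an explicitly supplied center — modeling
the osteotomy design that shifts the pivot to the middle of the maxilla —
then translates by (0, 10·Mxp, 10·Mxi) mm; the mandible (anterior
fragment, splinted to the maxilla) gets the same rotation about its own
center plus (0, 10·Mdp, 0) mm. Rotation angles are not part of published
planning tables, so the angle defaults to zero and must be supplied
explicitly. Jaw-surface node sets receive `u = T(p) − p` as Dirichlet
values; the posterior skull boundary is fixed; everything else is free.

## Evaluation metrics

**Facial surfaces** are compared with a bijective variant of surface
distance: for each node of surface A, `d_min` is the maximum of (i) its
shortest distance to surface B and (ii) the largest of the backward
shortest distances from B-nodes whose foot point on A is nearest to that
node. Taking the maximum avoids the artificially short values a
unidirectional distance yields between two nearby convex surfaces.
Distances are exact point-to-triangle (not vertex-to-vertex), computed
with a uniform-grid index whose results are bit-equal to the brute-force
loop; a vertex-to-vertex mode would be resolution-dependent and is not
the default. The backward assignment rule (nearest A-vertex to the foot
point, ties to the lowest index) is a deterministic choice the package
documents; the metric's definition leaves it open. Summaries (mean, sample
sd) are restricted to the *relevant region* where the simulated
displacement magnitude exceeds 0.1 mm, which excludes surface regions
dominated by acquisition noise from the comparison.

**Airways** are sliced by planes parallel to the palatal plane (through
ANS–PNS, superiorly oriented normal) at 1 mm spacing. Stations snap to
integer multiples of the spacing so pre-, post- and simulated profiles
share a grid. Each slice is chained into closed polygons; the largest-area
polygon is kept (the main air channel; discarded components are counted).
Area uses the shoelace formula; AP and Lat diameters are axis-aligned
extents along the in-plane projections of the anterior and lateral patient
axes — the clinical reading of "AP/lateral diameter" — rather than
principal-axis lengths. Outputs are reported in cm/cm², rounding to one
decimal only at report time. Region tags: velopharynx (VPX) between the
palatal plane and the soft-palate tip, oropharynx between soft-palate and
epiglottis tips, laryngopharynx (LPX) below; explicit station bounds can
override the landmark-derived ones, which the literature does not define
numerically. The narrowest section per region is the minimum-area station,
ties resolved inferior-most.

**Cohort statistics**: sample mean/sd/min/max per column (the n−1 sd is
what published planning tables print); the Sher surgical-success criterion
(>50 % AHI reduction and/or post-surgical AHI < 20/h); paired two-sided
t-tests over cross-section stations for each region × measure × pair
(pre/post, pre/sim, post/sim), binned into the conventional significance
classes. Duplicated patient rows (same id) are collapsed on ingestion with
a warning — the packaged table transcription deliberately preserves a
duplicated row from its source, and deduplication is what makes the
printed aggregates reproducible.

## The phantom

The phantom stands in for patient anatomy: a soft-tissue block with a
vertical airway tube that narrows to an hourglass constriction (the
velopharyngeal narrowing typical of OSA), rigid maxilla/mandible patches
on the anterior boundary, a fixed posterior (skull) boundary, and
landmarks that place the palatal plane at the top of the airway with
soft-palate and epiglottis tips partitioning VPX/oropharynx/LPX.

Construction: a conforming 6-tet (Kuhn) subdivision of a lattice, with
cells whose centroid falls inside the tube removed as a void. The airway
*surface* used for morphometry is an analytic tessellation of the tube
(rings at ≤ 1 mm, angular resolution tied to the lattice spacing), so
slice areas converge to the closed forms independently of the volume-mesh
staircase. Defaults: block 64 × 64 × 88 mm, tube radius 12 mm,
constriction radius 6 mm over a 12 mm half-extent at 65 % of the tube
height, lattice spacing 4 mm (≈ 31k elements) — sized so a nonlinear solve
takes on the order of a minute and a full pipeline run a few minutes,
while the narrowest-section area still matches the analytic constriction
to ≈ 1 %. Everything is deterministic in the parameters; the seed is
recorded for provenance and used only by jittered test fixtures.

What the phantom deliberately does *not* emulate: real facial geometry
and tissue heterogeneity, muscle anisotropy, tissue–bone sliding, tongue
posture and swallowing variability. Green tests on the phantom therefore
demonstrate the correctness of the machinery (solver, metrics,
statistics), not the clinical accuracy of predictions on real anatomy. In
particular, the synthetic "post-surgery" generator can apply a lateral
stretch factor (default scenario 1.3) to the deformed airway, emulating
the consistently reported finding that isotropic tissue models
under-predict the lateral widening of the velopharynx; the pipeline's job
is to *recover* that factor as the post/sim Lat ratio of the narrowest
section, which it does exactly by construction.

## Numerical choices and degenerate inputs

* Duplicate-vertex tolerance in validation: 1e-6 mm.
* Exact plane–vertex hits during slicing are nudged by 1e-12 mm so every
  crossing triangle contributes exactly one segment.
* Surface vertices are located in the volume mesh by best barycentric
  coordinate; the linear shape functions extend continuously outside an
  element, so vertices within a barycentric tolerance of 2 (relative to
  the containing element) are interpolated, and anything farther raises a
  containment error. This absorbs the lattice staircase around the
  analytic airway surface without affecting self-consistency comparisons,
  which always interpolate both surfaces identically.
* Landmark registration uses the closed-form Kabsch/SVD solution with
  determinant correction (reflections rejected); collinear landmark sets
  raise a degeneracy error. Landmarks match by name, never by order.
* Zero-variance paired differences: t = ±Inf with p = 0 and a degenerate
  flag (all-zero differences give t = 0, p = 1).
* Mesh-refinement behaviour: the narrowest-section prediction converges
  first order in the lattice spacing (the void boundary is a staircase),
  so successive refinements shrink the change between levels; the test
  suite asserts this contraction rather than a fixed percentage at a
  fixed resolution.

## Known limitations

* Isotropic, homogeneous elasticity: no muscle-fiber anisotropy, no
  tissue–bone sliding, no contact — the main reasons simulated lateral
  velopharyngeal widening underestimates reality.
* The mandible moves as one rigid anterior fragment; condylar
  repositioning is not modeled.
* Morphometry uses flat palatal-plane-parallel sections, not
  centerline-orthogonal resampling.
* The published planning tables carry one internal inconsistency (six
  laryngopharyngeal mean cells correspond to a nine-patient mean); the
  package reports full-cohort statistics and documents the difference in
  its tests rather than reproducing it silently.
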