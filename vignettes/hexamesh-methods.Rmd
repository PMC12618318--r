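---
title: "Methods: tet-to-hex conversion and head-neck FE preprocessing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tet-to-hex conversion and head-neck FE preprocessing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexamesh)
```

## Why convert tetrahedra to hexahedra

Subject-specific head models segment the brain, the cerebrospinal fluid
(CSF) layer and the surrounding structures from MR images. Tetrahedral
meshers follow the convoluted geometry of gyri, sulci and the thin CSF
pathways well, but nearly incompressible soft tissue (brain, CSF) is
simulated far more accurately with hexahedral elements. The conversion
implemented here replaces **every 4-node tetrahedron with four 8-node
hexahedra**, so a fine unstructured tet mesh of an arbitrarily complex
anatomy becomes a fine unstructured all-hex mesh with no re-meshing.

For one tetrahedron with vertices $V_1..V_4$ the inserted points are the
6 edge midpoints $M_{ij}$, the 4 face points $F_{ijk}$ (the vertex
average, i.e. the triangle centroid) and the element centroid $C$. The
hexahedron based at $V_1$ has the node cycle

$$(V_1,\, M_{12},\, F_{123},\, M_{13} \;|\; M_{14},\, F_{124},\, C,\, F_{134})$$

(bottom quad counter-clockwise, then top quad), and the other three
follow by vertex symmetry with orientation-preserving vertex orders.
Midpoints and face points on shared edges and faces are deduplicated
through canonical sorted-id keys, so neighbouring tetrahedra produce
conformal hexahedra and the output node count obeys the counting
identity $N = V + E + F + T$ (vertices + unique edges + unique faces +
tets). The four hexahedra partition the tetrahedron exactly, so total
volume is conserved to round-off before any smoothing.

The *face point is the centroid*, not any other interior point: only the
centroid construction reproduces the ideal worked example in which an
equilateral triangular face splits into three quadrilaterals with
interior angles 120° (at the centroid), 90°, 60° (at the vertex), 90°:

```{r}
predict_quad_angles(c(60, 60, 60))
```

## The 140° angle constraint

When a face deviates from the equilateral ideal, the quadrilateral at
the face point distorts; a right-isoceles face already produces a
143.13° corner. Angles approaching 180° degrade explicit-solver
accuracy, so all hexahedral face-corner angles are constrained to at
most 140° (configurable, `conversion_config(max_angle_deg = )`).

The enforcement mechanism was an open design point. We first evaluated
constrained Laplacian smoothing (inserted nodes relax toward the average
of their edge-connected neighbours). On lattice-derived test meshes this
is nearly a *fixed point*: by translation symmetry the inserted nodes
already sit at their neighbour averages, so the violating angles
(143°–145° at interior face points) are never repaired. We therefore use
**angle-driven constrained repositioning**: in each sweep, every face
corner whose angle exceeds the bound pushes its apex node along the
negative bisector of the two edge vectors meeting there, with a step
proportional to the violation and the local edge length (scaled by
`smoothing_relaxation`, default 0.5), aiming 2° below the bound so
repaired corners keep a margin.

Node motion is constrained by provenance:

* original vertices never move;
* edge midpoints slide only along their straight parent edge;
* face points move only within their parent face plane;
* element centroids move freely.

Under these constraints the three quads of every original triangular
face keep tiling that face exactly, so the input boundary surface and
the per-tet partition — hence the total volume — are preserved exactly
(the reported `volume_drift` is zero to round-off). This also covers
`preserve_boundary` for free; setting it to `FALSE` removes the sliding
constraints for applications that prefer more smoothing freedom over
geometric fidelity. Elements still violating the bound after the sweep
budget (`smoothing_iterations`, default 10) are *flagged, never
deleted*, mirroring the practice of routing a small residue of elements
to manual repair. On the lattice sphere fixture (radius 40 mm, cell
edge 2 mm, roughly 200k tets and 800k hexes) the procedure converges in
4 sweeps with nothing flagged; the test suite asserts the bound there.

A 2D pre-screen is available without building any mesh:
`predict_quad_angles(c(A, B, C))` constructs a representative triangle
with those interior angles, subdivides it and measures all twelve quad
angles.

## Quality metrics

The thresholds used during mesh generation are aspect ratio < 4,
skewness < 45°, warping < 20°, maximum face-corner angle ≤ 140°, and
scaled Jacobian > 0.4 (hexahedra) / > 0.8 (tetrahedra); summary tables
additionally report the percentage of elements with aspect ratio < 3.
Commercial meshers do not publish their metric formulas, so the standard
textbook definitions are used, under which those threshold values are
meaningful:

* **scaled Jacobian** — minimum over the element corners of the
  determinant of the three *unit* edge vectors meeting there (1 for an
  orthogonal corner frame; tetrahedra are additionally normalized by
  $\sqrt{2}/2$ so the regular tet scores 1). The four hexahedra of a
  unit regular tetrahedron score $\sqrt{1/2} \approx 0.707$ at the
  original-vertex corners (three unit edges pairwise at 60°), which is
  why converted meshes clear the 0.4 hex bound by construction.
* **aspect ratio** — longest element edge over shortest.
* **skewness** — maximum deviation of a face corner angle from the
  ideal (60° triangles, 90° quads), in degrees.
* **warping** — angle between the normals of the two triangles obtained
  by cutting a quad face along a diagonal, maximized over both diagonals
  (faces of a trilinear hex need not be planar).
* **mesh size** — mean ± SD of all element edge lengths, pooled per
  element, which reproduces the millimetre-scale values quoted in mesh
  summary tables.

All metrics are invariant under rigid motion; the scale-free ones
(scaled Jacobian, aspect, skewness, warping, angles) are also invariant
under uniform scaling. Both properties are asserted in the tests.

## Constitutive models

Internally the package uses the explicit-FE mm / ms / MPa convention;
densities stay in kg/m³ and Prony relaxation times in seconds, as
tabulated in the sources. The registry (`material_registry()`) carries
one preset per modelled structure: linear elastic skull / dura / pia /
vertebrae; linear viscoelastic scalp
($G(t) = G_\infty + (G_0 - G_\infty)e^{-\beta t}$, 1.70 → 0.68 MPa);
polynomial hyperelastic CSF and disks
($W = \sum C_{pq}(J_1-3)^p(J_2-3)^q + W_H(J)$); hyper-viscoelastic
white / gray matter ($W = \tfrac{\mu}{2}(I_1-3) + \tfrac{K}{2}(J-1)^2$
with normalized Prony series $G(t) = G_\infty + \sum G_i e^{-t/\tau_i}$);
Hill-type muscle; and linear ligament springs. Scalp elements rupture in
impact simulations, so the erosion rule removes elements whose maximum
principal Green–Lagrange strain exceeds 60% (`erosion_rule()`); the
strain measure is the standard choice for explicit-FE failure criteria
and is configurable.

Several tabulated values are ambiguous in the sources, and the package
resolves them explicitly rather than silently:

* the scalp decay constant β = 3e-5 is printed without a unit; it is
  stored with an explicit `beta_unit` tag (default 1/ms) that every
  curve export surfaces;
* the CSF coefficient C10 = 0.0112 is taken as MPa, consistent with the
  other rows of the table;
* the volumetric term $W_H(J)$ is unspecified; we use
  $\tfrac{K}{2}(J-1)^2$ with $K$ derived from near-incompressibility via
  $\mu = 2(C_{10}+C_{01})$, $K = 2\mu(1+\nu)/(3(1-2\nu))$;
* the disk Prony coefficients (1.70, 1.20, 2.00) sum to well over 1, so
  they are clearly not normalized; the registry stores and evaluates
  them exactly as printed;
* the Hill force-length and force-velocity shapes are cited, not
  printed; configurable standard forms are used (Gaussian force-length
  with width 0.5; Hill hyperbola force-velocity with shape 0.25 and the
  standard eccentric plateau), as are the unprinted passive constants
  (Ksh = 3, Lmax = 1.5). Derived quantities follow the stated
  conventions: resting length = volume / PCSA, maximum shortening
  velocity = 10 resting lengths per second, Fmax = 0.3 MPa × PCSA.

Two self-consistency checks are built into the constructors: the
normalized brain Prony series must satisfy $G_\infty + \sum G_i = 1$
within 2%, and $\mu_0 G_\infty$ must match the printed $\mu_\infty$
within 3% (both brain presets pass). Uniaxial Cauchy stress under
isochoric stretch is computed analytically from the invariant
derivatives and cross-checked against central finite differences of the
energy in the tests.

## Morphometry and validation statistics

Vertebral measures follow the corner-landmark convention: height is the
mean of the anterior and posterior body heights, depth the mean of the
superior and inferior widths, spinous process length the distance
between its distal and proximal corner points, and body-to-spinous
length the distance from the distal spinous point to the posterior body
wall (taken as the midpoint of the posterior corners). The dimensionless
disk height uses the angle-corrected construction: each vertebral
mid-plane is the line through the midpoints of the anterior and
posterior walls, the bisectrix halves the angle between the two
mid-planes, and the disk height — the gap between the facing endplate
midpoints measured perpendicular to the bisectrix — is normalized by the
mean body depth. The ratio is rigid-motion and scale invariant;
intersecting bodies yield a negative value with a flag.

Landmark picking is interactive in practice, so landmarks are *inputs*
(CSV `label,x,y,z`); the parametric-vertebra generator provides
ground-truth landmarks for testing. `pca_reorient()` reorients a
vertebral point cloud by matching its principal components, in
descending-variance order, to the global axes, with signs resolved
against caller-supplied anatomical reference directions; repeated
covariance eigenvalues (an isotropic cloud) are reported as degenerate
rather than silently resolved.

Surface thickness supports the two measurement modes used for scalp and
skull: the global minimum (minimum over outer-surface nodes of the
point-to-triangle distance to the inner surface) and site-based
measurements (distance along the inward ray from each site to the first
inner-surface intersection; hits beyond the inner surface's centroid
belong to the contralateral wall and are reported as missing, as are
rays through holes in a patch). Enclosed volumes use the divergence
theorem on closed oriented surfaces and report cm³.

The neck flexion angle is the angle between the vertical and the line
joining the anterior-most foramen magnum point to the anterior-inferior
C7 corner, both projected into the mid-sagittal plane; the sign
convention is positive for flexion (anterior rotation), since published
comparisons report magnitudes only. Curve comparison resamples the
second series linearly onto the first's time grid over the overlap and
reports the Pearson correlation, each curve's peak magnitude and peak
time, and the mean absolute value — the summary used when displacement
curves oscillate around zero.

## Synthetic fixtures and what they do (not) show

All test inputs are generated in code. Volume meshes come from a cubic
lattice in which each cell is split into six tetrahedra by a fixed
vertex-ordering template; because the template is identical in every
cell, face diagonals agree across cells and the mesh is conformal and
deterministic, with every tetrahedron positively oriented. Cells are
kept when their centroid satisfies the shape predicate (sphere, or
two-layer core/shell emulating brain-inside-CSF). The staircase boundary
approximates the smooth shape only in volume (within 5% at radius 10 mm
/ edge 1 mm), which is sufficient for exercising the conversion,
conformality and quality machinery; it does *not* exercise the highly
irregular element shapes of an anatomy-following tet mesh, so passing
tests bound the method's behaviour on well-shaped and lattice-degenerate
(right-tet) elements, not on arbitrary sliver populations. Slivers are
covered separately by the flagging contract: a sheared sliver is either
repaired below the bound or flagged, never dropped.

The damped-oscillation generator
($A e^{-\gamma t}\sin(2\pi f t)$ + seeded Gaussian noise) stands in for
validation curves; real experimental curves carry structured, not
Gaussian, noise, so the comparison statistics are tested for their
mathematical properties (r = 1 on identity, −1 on negation, ≈ 0 on
quadrature) rather than against any experimental claim. Strain-field
rules (uniform / radial / hotspot) drive the batch erosion checks with
exactly recountable outcomes.

Problem sizes used by the test suite and the acceptance script were
chosen to exercise the full pipeline at meaningful scale: the angle
criterion runs on the radius 40 mm / edge 2 mm lattice sphere
(≈ 201k tets → 805k hexes, ≈ 0.9M nodes), the property suites on random
sub-meshes of up to 50 tets where brute-force enumeration is exact, and
the remaining fixtures at radii 6–10 mm.

## Numerical choices

* Lengths in mm, angles in degrees, stresses in MPa; 1-based contiguous
  node ids internally (R convention) with original file ids preserved in
  an `orig_id` map, since FE exchange formats allow arbitrary 1-based
  ids.
* Tetrahedra with |volume| < 1e-12 mm³ are rejected as degenerate
  (below coordinate round-trip precision); duplicate coordinates under
  distinct ids produce a warning, not a merge.
* Hexahedra are emitted in tet order with vertex-1..4 sub-order;
  inserted node ids are assigned at the first canonical-key encounter —
  the conversion and the smoothing are fully deterministic, with no
  randomness anywhere.
* Face-corner angles are measured as the 3D angle between the two edge
  vectors at each corner of each of the six (possibly non-planar)
  faces, via `atan2(|u × w|, u · w)` for stability near 0° and 180°.
* The smoothing aims 2° below `max_angle_deg` and stops at the first
  sweep in which the audit passes; negative orientation on input is
  repaired on construction (tets by swapping two nodes, hexes by
  swapping bottom and top quads).
* Degenerate quality values are capped sentinels (aspect 1e6, scaled
  Jacobian 0) with the affected elements listed in an attribute, so
  reports never contain non-finite values.

## Known limitations

* The conversion quadruples the element count and inherits the input
  mesh's grading; it performs no coarsening, refinement or template
  optimization.
* Angle enforcement moves nodes; it never re-connects elements, so a
  tetrahedron whose *vertex* angles already exceed the bound (input
  triangles with corners > 140°) cannot be repaired and will be flagged.
* The keyword / .inp writers emit node, element and part cards only;
  solver settings (element formulations, hourglass control, contacts)
  appear as comments and are never parsed.
* Material evaluators are point/curve evaluators for model configuration
  and verification; they do not integrate stress inside a time-stepping
  solver, and anisotropic fibre-reinforced brain models are out of
  scope.
* The site-based skull thickness expects caller-supplied site
  coordinates; no EEG-convention site placement is attempted.
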