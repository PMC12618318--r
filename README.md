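# hexamesh

Finite-element preprocessing for subject-specific head–neck models, in R.

Detailed head models mesh the brain and the cerebrospinal fluid (CSF)
layer from MR segmentations. Tetrahedral meshers follow the convoluted
geometry of gyri, sulci and thin CSF pathways, but nearly incompressible
soft tissue is simulated far more accurately with hexahedral elements.
`hexamesh` implements the conversion that bridges the two: **every
4-node tetrahedron is replaced by four 8-node hexahedra** through its
edge midpoints $M_{ij}$, face centroids $F_{ijk}$ and element centroid
$C$ — the hex based at $V_1$ has node cycle
$(V_1, M_{12}, F_{123}, M_{13} \mid M_{14}, F_{124}, C, F_{134})$ —
with inserted nodes deduplicated on shared edges and faces so the output
stays conformal, and with all hexahedral face-corner angles constrained
to 140° by geometry-preserving, angle-driven smoothing. Each triangular
face splits into three quadrilaterals; for an equilateral face these
have interior angles 120°, 90°, 60°, 90°.

Around the conversion the package provides the supporting computations a
head–neck modelling workflow needs:

* **mesh I/O and core operations** — legacy/XML VTK, ASCII/binary STL,
  Abaqus-style `.inp` and LS-DYNA keyword readers/writers; boundary
  extraction, edge/face enumeration, volumes (`read_mesh`,
  `boundary_surface`, `mesh_volume`, ...);
* **quality metrics and reports** — scaled Jacobian, aspect ratio,
  skewness, warping, maximum corner angle, mesh-size statistics, with
  the acceptance thresholds 4 / 45° / 20° / 140° and Jacobian bounds
  0.4 (hex) / 0.8 (tet) (`quality_report`);
* **constitutive models** — evaluators and published presets for every
  modelled tissue: linear elastic bone and meninges, linear viscoelastic
  scalp `G(t)`, polynomial hyperelastic CSF/disks `W(J1, J2, J)`,
  hyper-viscoelastic brain (neo-Hookean + normalized Prony series),
  Hill-type muscle, ligament springs, and the 60% principal-strain scalp
  erosion rule (`material_registry`, `relaxation_modulus`,
  `hill_muscle_force`, `erosion_check`);
* **morphometry and validation statistics** — vertebral body height /
  depth, spinous process lengths, angle-corrected dimensionless disk
  height, PCA reorientation, surface thickness, enclosed volumes, neck
  flexion angle, maximum principal strain, and Pearson/peak/average
  curve comparison (`vertebral_measures`, `dimensionless_disk_height`,
  `curve_compare`);
* **deterministic synthetic fixtures** — lattice sphere and two-layer
  tet meshes, box lattices, parametric vertebrae with ground-truth
  landmarks, seeded damped-oscillation curves and strain fields
  (`sphere_tet_mesh`, `parametric_vertebra`, ...), so the whole test
  surface runs with no external data.

## Worked example

```r
library(hexamesh)

mesh <- sphere_tet_mesh(radius = 10, cell_edge = 2)  # lattice tet sphere
mesh
#> <tet_mesh> part 'sphere': 823 nodes, 3312 elements

res <- convert_tet_to_hex(mesh, conversion_config(max_angle_deg = 140))
res
#> <tet2hex_result> 3312 tets -> 13248 hexes (15853 nodes)
#>   inserted nodes: 4614 edge midpoints, 7104 face centroids, 3312 element centroids
#>   smoothing: 4 iteration(s), volume drift 0%
#>   max face-corner angle 139.76 deg, 0 flagged element(s)

quality_report(res$hex_mesh)
#> <quality_report> 13248 hex_mesh elements
#>   mesh size 0.81 +/- 0.34 mm; min scaled Jacobian 0.408
#>   aspect < 3: 0.0%; max corner angle 139.8 deg (100.0% within 140)
```

The conversion produced exactly four hexahedra per tetrahedron and one
inserted node per unique edge, face and element (13248 = 4 × 3312;
15853 = 823 + 4614 + 7104 + 3312). Four smoothing sweeps brought every
face-corner angle under the 140° bound with zero flagged elements, and
the constrained node motion preserved the boundary and total volume
exactly ("volume drift 0%"). The minimum scaled Jacobian 0.408 clears
the 0.4 hexahedral acceptance bound; the low "aspect < 3" percentage is
inherent to tet-derived hexahedra, whose edges mix half-edges, face
fractions and centroid links.

The ideal-face angle prediction and a material curve:

```r
predict_quad_angles(c(60, 60, 60))
#>      vertex midpoint centroid midpoint
#> [1,]     60       90      120       90
#> [2,]     60       90      120       90
#> [3,]     60       90      120       90

scalp <- material_preset("scalp")
relaxation_modulus(scalp, c(0, 1e4, 1e5, 1e12))   # t in 1/beta_unit
#> [1] 1.7000000 1.4356346 0.7307828 0.6800000
```

The scalp shear modulus relaxes from G0 = 1.70 MPa toward
G∞ = 0.68 MPa, and the equilateral subdivision reproduces the
120/90/60/90 quadrilateral exactly.

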