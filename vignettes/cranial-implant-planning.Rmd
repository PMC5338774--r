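---
title: "Planning cranial implants from mirrored skull templates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning cranial implants from mirrored skull templates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranioplan)
```

## The planning problem

Cranioplasty repairs a defect in the cranial vault with a
patient-specific implant. The planning input is a CT-derived surface
mesh of the defect skull (STL, millimetres); the output is a watertight
implant surface that fills the defect flush with the surrounding bone.
`cranioplan` implements a scriptable version of the mirror-template
workflow: because the healthy hemisphere is the best available estimate
of the missing anatomy, the skull is reflected across the midsagittal
plane and the reflected surface serves as a curvature template over the
defect. Since real heads are noticeably asymmetric, pure mirroring is
not sufficient; the template is only a scaffold on which landmarks are
placed and then regularised.

The pipeline has three blocks, mirrored by `plan_implant()`:

1. **Dataset preparation** — load the STL (`read_stl()`), centre it
   (`center_mesh()`), duplicate and reflect it (`reflect_mesh()`),
   optionally register the template onto the original with landmark
   Procrustes (`rigid_register()`).
2. **Marker setting** — typed landmarks: outer edge (0) and inner
   edge (1) markers on the defect rim; outer surface (2) and inner
   surface (3) markers on the template. Types {0,2} form the outer
   layer, {1,3} the inner layer.
3. **Final adjustments** — constrained Laplacian smoothing of the
   marker cloud (`smooth_markers()`), 3D Delaunay tetrahedralization
   (`delaunay_tetrahedralize()`), alpha filtering (`alpha_filter()`),
   boundary-surface extraction and STL export.

## The constrained smoother

One smoothing pass moves every *surface* marker to the weighted mean of
its same-layer neighbours within radius $x$:

$$\vec{x}_i \leftarrow \frac{\sum_j w_j\,\vec{x}_j}{\sum_j w_j},
\qquad w_j = \begin{cases} y & \text{edge marker} \\ 1 &
\text{otherwise} \end{cases}$$

With $y = 1$ this is the classic Laplacian update
$\vec{x}_i = \frac{1}{N}\sum_{j=1}^{N}\vec{x}_j$ over the $N$ adjacent
markers (the marker itself excluded). Edge markers never move: they
were placed on the defect rim and are treated as ground truth, which
both anchors the implant to the bone and counteracts the shrinkage any
Laplacian smoother causes. Design decisions worth knowing:

* **Simultaneous (Jacobi) update.** All new positions are computed from
  the old ones, so the result is independent of marker order. A
  sequential in-place loop would not be.
* **Layers never mix.** Outer markers average only over outer-layer
  neighbours, inner over inner; otherwise the two tables of the implant
  would collapse towards each other.
* **$x$ is a radius (mm), $y$ a weight (dimensionless $\ge 1$).** The
  radius criterion is inclusive (distance $\le x$). A marker with no
  neighbour in range stays put.
* **Defaults: $x = 6$ mm, $y = 2$, one iteration.** The radius is
  deliberately below the typical spacing of a well-spread marker set
  (about 8–9 mm for 40 markers on a palm-sized defect), so default
  smoothing regularises clustered or hand-placed markers without
  displacing an already even cloud; raising $x$ to 1.5–2 times the
  marker spacing gives the strong aesthetic smoothing pass at the cost
  of some volumetric shrinkage. Fewer than three markers dismiss the
  operation.

## Delaunay triangulation and the alpha filter

The marker cloud is tetrahedralized with an incremental Bowyer–Watson
Delaunay algorithm written for this package (no 3D Delaunay backend is
assumed). Marker clouds offset from smooth skull surfaces are nearly
cospherical — the classic degenerate input — so degeneracies detected
during insertion (singular circumcentre systems, flat cavity
tetrahedra, failed post-validation) trigger a deterministic retry with
symbolic-style jitter: pseudo-random offsets of 1e-9 mm from a fixed
internal seed, escalated tenfold per retry up to 1e-5 mm. Circumradii
are always reported from the unjittered coordinates. Every accepted
triangulation passes structural validation: positive orientation, at
most two tetrahedra per face, a closed boundary surface, and agreement
between summed tetrahedron volume and the boundary-surface volume.

The Delaunay complex fills the convex hull, but an implant for a
curved shell is concave on the inside. Alpha filtering keeps only
tetrahedra with circumradius $\le \alpha$: the huge tetrahedra
bridging the concave inner side have circumradii on the order of the
skull's local radius of curvature (tens of mm), while genuine shell
tetrahedra are on the order of the marker spacing, so a wide band of
$\alpha$ values separates the two.

`plan_implant()` chooses $\alpha$ automatically: it scans the sorted
circumradius spectrum for the smallest value at which the kept complex
uses every marker and bounds a *closed* surface (the solidification
threshold), then takes the smallest closed value at least 1.5 times
that threshold. At the bare threshold the boundary still detours
around single missing tetrahedra; the 1.5 margin closes those dents
while staying several times below the hull-spanning circumradii. The
standalone `triangulate` CLI subcommand defaults to no filtering
(`alpha = none`), since outside the pipeline the right threshold
depends on marker spacing the tool cannot presume.

## Automatic marker placement

The interactive workflow this package automates has a user clicking
markers; headless runs need a reproducible stand-in:

* **Edge markers** resample the defect rim loops
  (`boundary_loops()`, `place_edge_markers()`) uniformly by arc
  length, half on the outer-table rim (type 0), half on the
  inner-table rim (type 1). The inner ring is staggered half a step so
  the two rim polygons interleave and their chord cuts do not align.
* **Surface markers** are drawn from the mirrored template restricted
  to outward-facing faces (the outer table of the two-layer shell)
  inside the rim polygon — per direction from the rim centroid, faces
  nearer than the angularly-nearest rim marker. From a seeded
  area-uniform pool (`place_surface_markers()`, eight times
  oversampled) the `n_surface` points are kept by greedy
  farthest-point thinning, emulating the even spacing of manual
  clicks. Inner-surface markers reuse the same base sample offset
  inward along the local normal by the shell thickness (default 4 mm),
  since mirrored STL templates often do not resolve the inner table;
  the offset heuristic is this package's choice.

All stochastic steps descend from the single config seed, so a plan is
reproducible bit for bit: the same config yields a byte-identical
implant STL.

## Evaluation metrics

Agreement between two implants (or an implant and a phantom's ground
truth) is measured volumetrically on a shared isotropic voxel grid
(default 0.5 mm): Dice similarity coefficient
$\mathrm{DSC} = 2|A \cap B| / (|A| + |B|)$ in percent, Hausdorff
distance between occupied-voxel centre sets in voxel units, and
volumes in voxels and mm³. Voxelization uses parity ray casting along
+x with a fixed 1e-7 mm ray offset so rays never graze triangle edges;
meshes must be watertight. Hausdorff distances are computed exactly:
only voxels outside the other set can attain the maximum, and their
nearest neighbour always lies on the other set's 6-connected boundary,
so both sets are reduced before the chunked distance scan.

## The synthetic phantom

`generate_phantom()` builds a thin curved shell between an ellipsoid
(default semiaxes 70 × 85 × 60 mm, adult half-calvaria proportions)
and its inward normal-offset (thickness 4 mm, locally uniform by
construction rather than a scaled copy), on a subdivided icosahedron
basis. A conical wedge around a defect axis (default a right parietal
direction, half-angle 25°) is removed with the rim left open; the
removed wedge closed by a rim wall is the watertight ground-truth
patch. An asymmetry factor scales the x > 0 half to emulate real
left/right asymmetry. The phantom exercises every pipeline stage —
curvature, two tables, an open rim, mirrorability — but it is smooth
and noise-free: passing against it shows geometric correctness of the
pipeline, not robustness to segmentation noise, bone texture, or
anatomical detail of clinical CT surfaces.

End-to-end tests plan an implant on the default symmetric phantom with
24 edge + 40 + 40 surface markers and default parameters and require a
watertight result with DSC ≥ 85 % against the truth patch at 0.5 mm
spacing. The remaining disagreement is structural and understood:
chord cuts of the 12-gon rim rings, flat faceting of both curved
boundary layers, and voxel quantisation.

Numerical problem sizes used throughout the tests — subdivision 3
phantoms (1280 faces per table; subdivision 4 for the shell-volume
convergence check), 104 markers, 0.5 mm grids of roughly 10⁵–10⁶
voxels — were chosen as the smallest sizes at which the geometric
properties under test are clearly resolved.

## Questionnaire summaries

`likert_summary()` reports, per item, the arithmetic mean and the
standard error of the mean computed from the *population* standard
deviation (divide by $n$), both rounded half-up to two decimals —
the conventions of small-sample software-ergonomics tables on 1–6
Likert scales. Published tables of this kind sometimes label the mean
column "Median" and occasionally truncate rather than round
(0.8165 printed as 0.81); the package always computes the mean and
rounds half-up, and the test suite documents the truncation cases
explicitly rather than asserting them blindly.

## Known limitations

* Clipping drops crossing faces rather than splitting them; it is a
  marker-placement aid, not implant geometry.
* Registration is landmark-based with exact correspondences; no
  iterative closest point or deformable matching.
* The Bowyer–Watson implementation targets marker-cloud sizes
  (hundreds of points); it is not tuned for large point sets.
* The defect region for automatic placement is derived from the rim
  polygon; exotic rim shapes (strongly non-star-shaped) would need an
  explicit marker file instead.
* Inner-surface markers rely on the constant-thickness offset
  heuristic; where the true inner table deviates (sinuses, diploë
  variation), manual inner markers are the remedy.

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_spec())
plan <- plan_implant(plan_config(input = ph$defect, seed = 1,
                                 output_stl = "implant.stl"))
print(plan)
grid <- grid_for_meshes(list(plan$implant, ph$truth), 0.5)
dice_coefficient(voxelize(plan$implant, grid = grid),
                 voxelize(ph$truth, grid = grid))
```
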