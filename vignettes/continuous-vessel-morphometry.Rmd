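---
title: "Continuous morphometry of tubular vascular surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous morphometry of tubular vascular surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselgauge)
```

## The measurement problem

Clinical surveillance of thoracic aortic disease has traditionally relied
on maximum-diameter measurements at a handful of anatomical stations,
taken by a reader on reformatted image planes. Such discrete measurements
are labor-intensive, sensitive to the reader's choice of plane and
position, and blind to everything that happens between stations — the
extent of a dilation, the exact position and depth of a coarctation, or
out-of-round (asymmetric) remodeling of the cross-section.

`vesselgauge` implements the continuous alternative: starting from a
triangulated lumen surface, it

1. extracts an interior **centerline** between inlet and outlet,
2. samples planes **normal to the centerline** every 2 mm and measures the
   **maximum diameter** (largest point-pair distance of the section
   contour) and **cross-sectional area** (shoelace) at every station,
3. computes centerline **tortuosity** (arc length over endpoint chord) and
   the **curvature at the arch apex**,
4. maps the per-vertex **Euclidean distance** from the wall to the
   centerline (the size/asymmetry field),
5. registers follow-up surfaces rigidly (landmark fit refined by iterative
   closest point) and renders visit-to-visit change as a **signed surface
   distance map**, and
6. provides the **method-agreement statistics** used to compare the
   continuous method against manual readings: least-squares correlation,
   Bland–Altman bias and limits of agreement, Passing–Bablok regression,
   and a variance-ratio concordance test for visit-to-visit changes.

Because no patient imaging data can ship with the package, every claim the
package makes about itself is validated on **parametric phantoms with
closed-form ground truth** (the `phantom_spec()` / `make_phantom()`
module). The phantom is a first-class, tested component, not a fixture.

## The phantom generator and what it emulates

The phantom is a "candy-cane": a straight ascending segment, a
semicircular arch of radius $R$, and a straight descending segment, swept
with elliptical cross-sections. Arc length $s$ runs from 0 at the
ascending inlet. On top of the base tube the spec can impose

* a **coarctation**: a Gaussian multiplicative narrowing
  $r(s) = r_0\,[1 - d\,e^{-(s-c)^2/2w^2}]$ with depth fraction $d < 1$,
* a **dilation patch**: an additive Gaussian bulge, optionally restricted
  to a raised-cosine angular window (to emulate one-sided aneurysmal
  bulging), and
* **branch stubs**: short cylinders planted on the arch outer wall, used
  solely to exercise branch-exclusion logic. The stub–wall junction is
  left as touching open rims rather than a watertight boolean union; this
  reproduces exactly the feature the pipeline must detect (an open ostium
  contour) without a CSG engine. Stub-free phantoms are watertight.

Because section radii, centerline, tortuosity ($L/\text{chord}$) and apex
curvature ($1/R$) all come from the same formulas, the generator returns a
ground-truth object with vectorized `max_diameter(s)`, `area(s)`,
`max_radius(s)` functions — the repository's central oracle.

What the phantom deliberately does **not** emulate: imaging noise
structure (partial-volume effects, bias fields), true anatomical shape
variation (no statistical shape model), branch vessels with flow-split
geometry, or wall motion. Passing phantom tests therefore demonstrates
that the measurement machinery is correct and calibrated, not that
segmentation of noisy clinical images is solved.

Default study conditions used by the tests and the acceptance script:
cylinder $r = 12.5$ mm, $L = 100$ mm; arch $R = 40$ mm, $r = 10$ mm;
coarctation tube $d = 24$ mm base diameter, depth 0.5, Gaussian width
12 mm centred at $s = 150$ mm of a 300 mm tube; mesh resolution about one
ring per mm with 64 circumferential vertices. These sizes give run times
of seconds per phantom on one CPU while keeping discretization error an
order of magnitude below the tolerances being tested.

## Centerline extraction

The reference tooling in this field traces centerlines as weighted
shortest paths that ride the Voronoi diagram of the lumen, i.e. the locus
of maximal inscribed spheres. `vesselgauge` realises the same centrality
contract with a transparent, fully testable construction:

1. the lumen interior is voxelized by ray-crossing parity (open inlet and
   outlet rims are temporarily capped with centroid fans), at a default
   pitch of 1 mm, refined automatically if the vessel is thin;
2. the wall distance of every interior voxel is computed with an exact
   Euclidean distance transform;
3. the centerline is the minimum-cost path on the 26-neighbour voxel graph
   with edge cost $\ell / d^p$ ($p = 2$), found by Dijkstra's algorithm
   (via igraph) with deterministic tie-breaking — the $d^{-p}$ penalty
   drives the path onto the ridge of maximal inscribed spheres;
4. the raw voxel path is refined onto the medial locus by a pattern
   search in the plane normal to the local tangent, maximizing the
   *exact* point-to-surface distance. Accepted moves strictly increase
   wall clearance, so the refinement can neither leave the lumen nor
   diverge; it converges to sub-0.05 mm residuals from a 1 mm voxel path;
5. the path is pinned to the supplied endpoints, smoothed by an
   arc-length moving average with pinned endpoints, and resampled at
   0.5 mm. The inscribed radius is re-measured as the exact distance to
   the original surface.

The voxel graph alone leaves a systematic half-pitch offset (no voxel
centre need lie on the true axis); the medial refinement step is what
brings the cylinder-axis recovery from $\approx 0.7$ mm down to
$\approx 0.02$ mm.

### Curvature and tortuosity

Curvature is estimated by the circumscribed-circle (Menger) formula on
point triples 2 mm apart — the same spacing as the measurement planes, a
deliberate compromise between stencil noise amplification (small spacing)
and curvature smearing (large spacing). Because a three-point stencil
amplifies residual millimetre-scale ripple of the discrete path, the
*apex* curvature is reported as the median of the profile within ±5 mm of
the apex (the point furthest along a user-supplied elevation axis; the
package does not guess scanner orientation). On the semicircular arch
phantom this estimator is within 0.5% of $1/R$, while the raw single-point
stencil wanders by several percent.

Tortuosity is the total arc length divided by the endpoint chord — it is
exactly 1 for a straight vessel and $\pi/2$ for a semicircle, both of
which the suite checks end to end through mesh, voxel graph and
refinement.

## Cross-sectional profiles

At each station the mesh–plane intersection is chained from per-triangle
segments, welded on shared mesh edges so closed section curves close
exactly. The loop enclosing the centerline point is kept (the smallest
enclosing loop if several; planes through the arch cut both limbs).
Maximum diameter is the largest point-pair distance of the contour,
computed on the convex hull — deliberately *not* an ellipse-fit axis or
twice the centroid distance, because clinical sections are not elliptical
and the full circumferential information is exactly what the continuous
method is for. Area is the shoelace magnitude.

A station is excluded, never silently dropped, when

* the section is an **open contour** — the plane cut a rim or a branch
  ostium;
* it falls in a user-declared **branch window** (arc-length span); or
* its area jumps by more than 30% relative to *both* neighbours (the
  automatic ostium flag).

Visits are aligned by a single rigid arc-length shift at one matched
landmark (alignment "at the branches"); piecewise warping is deliberately
rejected because it would invent correspondences the data do not contain.
Growth or shrinkage is called per station when the aligned diameter
change exceeds a threshold, 1.5 mm by default — the scale of
inter-observer variability of manual readings (about one pixel), below
which change cannot be distinguished from measurement noise.

## Distance maps and asymmetry

`euclidean_field()` assigns every surface vertex the distance to its
nearest centerline sample (0.5 mm resampling keeps the chord error below
0.05 mm; the k-d tree query is checked against an exhaustive scan in the
tests). For branched vessels a list of centerlines is pooled so ostium
vertices bind to their branch path. Regional summaries (ascending / arch
/ descending) split vertices by the arc length of their nearest
main-path point at two explicit cut points — the package does not infer
anatomy. The per-station asymmetry index $(\max - \min)/\text{mean}$ of
the field is 0 for circular sections and $\approx 0.4$ for a 3:2 ellipse,
matching the closed form.

## Registration and change maps

Visit-to-visit registration is rigid only — landmark Kabsch fit, then ICP
with exact closest-point-on-surface correspondences and a Kabsch update
per iteration. Rigidity is a modelling decision, not a limitation: any
scaling or deformation absorbed by the registration would be growth
deleted from the change map. Correspondences farther than 10× the median
are rejected each iteration (robustness near clipped rims), the RMS is
non-increasing by construction, and divergence (five consecutive RMS
rises) is an error, not a warning. Near-axisymmetric shapes (a plain
cylinder) leave a rotational null space; the guarantee is the surface
RMS, not pose uniqueness.

The change map assigns each registered target vertex its exact
point-to-triangle distance to the reference surface, signed by the
outward reference normal at the closest point: positive = outside =
growth. The sign convention, antisymmetry under swapping visits, and the
+1 mm calibration against a normal-offset surface are all tested.

## Voxel segmentation

Window thresholding (default 310–640 grey values, a scanner-specific
default retained for documentation, not a claim of generality) with
removal of small 26-connected components mirrors the standard
threshold-segmentation stage. Isosurfaces are extracted at the 0.5 level
by marching over the six-tetrahedra decomposition of each grid cube with
linear interpolation — watertight by construction through shared-edge
vertex welding, and with outward orientation fixed by the enclosed-volume
sign. A binary mask is first anti-aliased with a 1-voxel Gaussian;
without it the staircase of the binary level set inflates areas of
smooth solids, with it the voxelized $r = 20$ mm sphere's area is
recovered to 0.3% at 1 mm spacing and the error decreases monotonically
with grid refinement. The tetrahedral decomposition was chosen over the
classical 256-case cube tables because it is derivable from first
principles in a few dozen lines — every case is an even permutation of
one canonical tetrahedron configuration — which makes the kernel fully
reviewable; the cost is about twice as many triangles per unit area.

## Numerical choices and degenerate inputs

* Vertex welding at $10^{-6}$ mm; STL is a triangle soup and all topology
  checks (edge-manifoldness, boundary loops, orientation) run after
  welding. Binary STL output quantizes to float32 *before* computing
  facet normals, so write–read–write cycles are byte-identical.
* Taubin $\lambda|\mu$ smoothing with pass-band $k_{pb} = 0.02$
  ($\lambda = 0.5 \Rightarrow \mu \approx -0.505$): 30 default iterations
  change a closed surface's volume by $\approx 0.1\%$ and melt
  $\sigma = 0.3$ mm surface jitter by more than half, while plain
  Laplacian smoothing would shrink the vessel.
* Plane sections that touch mesh vertices exactly produce duplicate
  chain points; these are collapsed before metrics, and the
  self-intersection guard uses a scale-relative epsilon so degenerate
  zero-area crossings are not misreported.
* The Passing–Bablok estimator follows the original shifted-median
  procedure: pairwise slopes $S_{ij}$, slopes equal to $-1$ excluded,
  offset $K$ = number of slopes below $-1$, confidence bounds from the
  rank-based normal approximation. Ties in $x$ with untied $y$ contribute
  $\pm\infty$ slopes at the extremes of the order statistics.
* Bland–Altman uses the sample SD ($n-1$); the reproducibility
  coefficient is $1.96\,\mathrm{SD}$ so the limits of agreement span
  twice the coefficient by construction.
* The variance-ratio concordance test places the larger variance in the
  numerator and therefore takes its critical value at $1-\alpha/2$, so
  the test has overall size $\alpha$; with the critical value at
  $1-\alpha$ the null rejection rate would double to $\approx 10\%$,
  which the Monte-Carlo test in the suite would reject.
* All randomness (phantom noise, ICP subsampling, statistical
  simulations) is seeded through explicit `seed` arguments; RNG state is
  restored on exit so library calls do not perturb user sessions.

## A worked phantom example

```{r example, eval = FALSE}
ph <- make_phantom(phantom_preset("coarctation"), capped = FALSE)
cl <- compute_centerline(ph$mesh, c(0, 0, 0), c(0, 0, 300))
prof <- measure_profile(ph$mesh, cl, spacing = 2)
geom <- centerline_geometry(cl)

i <- which.min(prof$max_diameter_mm)
prof[i, ]                    # 12 mm at s = 150 mm: the constriction
geom$tortuosity              # 1.000 for a straight tube
autoplot(prof)               # diameter vs arc length, exclusions shaded
```

## Known limitations

* Mesh repair is limited to welding, degenerate/duplicate-face removal
  and orientation; non-manifold scanner exports beyond that are rejected
  rather than patched.
* Branch-stub phantoms are not watertight at the junction (by design, see
  above), so enclosed-volume checks apply only to stub-free phantoms.
* The centerline is defined between two endpoints; full bifurcating-tree
  centerlines beyond the main vessel plus straight branch paths are out
  of scope.
* Registration is rigid; deformable or atlas-based registration is
  explicitly not attempted.
* Anatomical landmark detection is not attempted anywhere: station
  positions, region boundaries and elevation axes are explicit arguments.
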