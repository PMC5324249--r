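# vesselgauge

Continuous morphometry of tubular vascular surfaces in R.

Surveillance of thoracic aortic disease is still mostly done by measuring
the maximum aortic diameter at a few anatomical stations on reformatted
image planes. That approach is reader-dependent and blind to everything
between stations: the extent of a dilation, the exact depth and position
of a coarctation, or out-of-round remodeling of the lumen. `vesselgauge`
implements the continuous alternative, end to end:

* **Centerline** — the interior path between inlet and outlet, traced as
  a wall-distance-weighted shortest path on the voxelized lumen and
  refined onto the medial locus (maximal inscribed spheres); tortuosity
  `L / chord` and arch-apex curvature (three-point circumscribed circle,
  2 mm stencil) come with it.
* **Continuous profile** — planes normal to the centerline every 2 mm;
  per station the **maximum diameter** (largest point-pair distance of
  the section contour) and **cross-sectional area** (shoelace), with
  automatic exclusion of open contours and branch windows, visit
  alignment at a landmark, and growth/shrinkage classification above a
  1.5 mm threshold (the scale of manual inter-observer variability).
* **Euclidean distance map** — per-vertex distance from the lumen wall to
  the centerline; regional means/maxima and a per-station asymmetry index
  `(max − min)/mean` that is 0 for circular sections.
* **Registration & change maps** — landmark (Kabsch) alignment refined by
  iterative closest point, rigid only, then a signed point-to-triangle
  surface distance on the registered pair: positive = growth.
* **Method agreement** — least-squares correlation, Bland–Altman bias and
  1.96 SD limits of agreement, Passing–Bablok regression (original
  shifted-median procedure), and a variance-ratio (F) concordance test
  for visit-to-visit changes.
* **Segmentation & phantoms** — grey-value window thresholding of voxel
  volumes (NIfTI) with isosurface extraction, and a parametric
  "candy-cane" aorta phantom generator (coarctation, dilation patches,
  elliptical sections, branch stubs) with closed-form ground truth that
  backs the entire test suite.

Surfaces are exchanged as STL (both dialects), volumes as NIfTI, scalar
color maps as PLY, tables as CSV; tabular results are tibbles with
`autoplot()` methods, and agreement reports have `tidy()`/`glance()`
methods.

## Worked example

```r
library(vesselgauge)

# a coarctation phantom: 24 mm tube, depth-0.5 Gaussian narrowing at s = 150
ph <- make_phantom(phantom_preset("coarctation"), capped = FALSE)
cl <- compute_centerline(ph$mesh, c(0, 0, 0), c(0, 0, 300))
prof <- measure_profile(ph$mesh, cl, spacing = 2)

prof[which.min(prof$max_diameter_mm), ]
#> # A tibble: 1 x 5
#>    s_mm max_diameter_mm area_mm2 excluded reason
#>   <dbl>           <dbl>    <dbl> <lgl>    <chr>
#> 1   150            12.0     113. FALSE    NA

centerline_geometry(cl)$tortuosity
#> [1] 1.000002
```

The profile minimum of 12.0 mm at arc length 150 mm recovers the
phantom's analytic constriction (depth 0.5 of a 24 mm base diameter,
centred at 150 mm) to within a station; the tortuosity of a straight
tube is 1 by definition. `autoplot(prof)` draws the diameter-versus-arc-
length line plot with excluded spans shaded.

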