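---
title: "Per-tree terrain correction of LiDAR canopy heights: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-tree terrain correction of LiDAR canopy heights: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canoheight)
```

## The problem

Airborne LiDAR canopy heights are conventionally computed per return:
`h = z - DEM(x, y)`, subtracting the bare-earth elevation directly under
each laser hit. For a tree on sloping ground this is geometrically wrong.
The height of a crown point should be measured against the elevation where
the *trunk* enters the ground, not against the ground vertically below the
point. On a uniform slope of angle $i$, a return a horizontal distance $c$
upslope of the trunk is depressed by $c\tan i$ and a downslope return is
elevated by the same amount; over a crown of diameter $d$ the error reaches
$(d/2)\tan i$ at the crown edge. At 30–50° slopes and 10–15 m crowns this
is metres, not centimetres — large enough to move detected treetops
downslope, distort segmented crowns, and bias every height-derived forest
parameter.

```{r}
round(max_difference_table(), 2)
```

## The correction

The package implements per-tree normalization:

1. **Group by crown.** First-return vegetation points are assigned to crown
   polygons (from an external segmentation, or the simulator's truth
   polygons); returns inside no crown are forest-gap points.
2. **Locate the tree base.** For group $i$ with points
   $(x_{ij}, y_{ij}, z_{ij})$ and DEM elevations $A_{ij}$ under them, the
   planimetric centre of gravity is the height-weighted mean

   $$x_{ig} = \frac{\sum_j x_{ij}\,w_{ij}}{\sum_j w_{ij}}, \qquad
     w_{ij} = z_{ij} - \tfrac1n \sum_j A_{ij},$$

   and likewise $y_{ig}$. For an upright tree the crown apex — where the
   tallest, hence heaviest, returns concentrate — sits over the trunk, so
   the centre of gravity is a proxy for the base position.
3. **Renormalize rigidly.** The base elevation $z_{ig}$ is the DEM value at
   $(x_{ig}, y_{ig})$; every member's corrected height is
   $z_{ij} - z_{ig}$. Within a crown this is a single vertical shift, so
   crown morphology (every pairwise height difference) is preserved
   exactly — the property the conventional method destroys.

Gap returns keep conventional heights; those at or below the 1.8 m
vegetation threshold are removed by default, mirroring the standard
practice of excluding shrub-layer and ground clutter from forest metrics.

### Numerical choices

* **Negative weights are clamped to zero.** The weight formula can go
  negative for returns below the group's mean ground elevation, which is
  pathological after vegetation thresholding; clamping keeps the centre a
  convex combination of member positions. A group with no positive weight
  is reported degenerate and skipped with a warning.
* **$z_{ig}$ is sampled bilinearly**, not nearest-cell, to avoid
  quantizing the base elevation to the 0.3 m DEM grid.
* **Boundary points** of a crown polygon (and points in overlapping
  polygons) go to the lowest crown id, a deterministic tie-break.
* Groups of fewer than 3 returns are corrected but flagged low-confidence.

## Supporting stages

**Ground filtering** is a multiscale curvature classification: per pass, a
provisional surface is interpolated from the current ground candidates at a
given post-spacing, smoothed with a 3×3 mean kernel, and candidates more
than the curvature tolerance (default 0.05 m) above it are relabelled
vegetation; passes repeat to convergence over three scale domains (1.5×,
1.0×, 0.5× the nominal 1.5 m post-spacing, coarse to fine). The surface is
a penalized thin-plate spline (`mgcv`) over cells represented by their
lowest return at that return's true position; thin-plate splines carry the
planar trend in their null space, so sloping terrain is reproduced exactly
and only genuine curvature is penalized. Points below the surface are never
discarded. Because the early, canopy-contaminated passes can transiently
push ground returns past the tolerance in the smoothing ring around a tall
crown, a final symmetric pass relabels all points against the converged
surface; vegetation sits metres above it and does not leak back.

**Gridding** (DEM, DSM, CHM) is inverse-distance weighting with power 2
over the 12 nearest points within a search radius (default 10 cells),
0.3 m cells, grid origin at the lower-left cell centre. Under a fully
occluding crown the nearest ground returns are at the footprint edge, so
pipelines with large crowns must widen `max_radius` past the crown radius.

**Tree extraction** uses strict local maxima over a square window (default
3 m) above 1.8 m, and a marker-based watershed on the inverted CHM seeded
at the apices and masked to cells ≥ 1.8 m. The published
morphological-control and region-growing refinements are deliberately
simplified to this standard marker-controlled form.

**Plot statistics**: exceedance proportions $p_k$ and conditional means
over the per-point correction differences at
$k \in \{0.3, 0.5, 0.8, 1.0, 1.2, 1.5\}$ m; height deciles
$h_{10}..h_{90}$ (type-7 quantiles — the source work never states its
percentile rule) and mean height above 1.8 m; Lorey's height
$L_h = \sum G_i h_i / \sum G_i$ with $G_i = \pi(\mathrm{dbh}_i/200)^2$;
and a forward-stepwise OLS of $L_h$ on the ten percentile metrics where
each step adds the predictor that most improves the pooled K-fold
cross-validated $R^2$, stopping when none does. Forward-only selection is
the minimal reading of a "maximum K-fold R-square improvement" rule;
bidirectional elimination was considered and rejected as underdetermined
at n = 41 plots. Folds are seeded and stratified by response decile.

## The synthetic scene generator

No real flight data ships with the package, so every stage is validated
against simulated scenes with known truth: planar terrain of given slope
and aspect (optionally plus a smooth cosine-mixture roughness field —
smooth rather than white, so curvature-based filtering stays meaningful),
parametric spheroid or cone crowns, and Poisson-sampled first returns at
15 points/m² — the density and the 0.3 m DEM cell of the airborne survey
conditions the method targets. Crown footprints fully occlude the ground
(the hardest case for DEM interpolation under canopy); crown returns lie
on the upper envelope of the crown solid, one deterministic return marks
each apex so height-recovery metrics measure correction error rather than
sampling-gap error, and overlapping crowns resolve to the higher envelope.
Tree heights of 8–16 m with ~2 m crown-base heights and 3–10 m crowns
match the broadleaf stands that motivate the method. Scenes are
deterministic given their seed.

What the generator does **not** emulate: within-crown penetration and
multiple returns, scan-angle geometry, intensity, understory vegetation,
tilted stems, and rough micro-topography under crowns. Passing tests
therefore demonstrate the geometric correctness and statistical behaviour
of the correction, not end-to-end accuracy on real forests.

## Evaluating the geometry against an exact reference

The package evaluates its geometric properties (closed-form bias,
sign structure, the $(d/2)\tan i$ bound) against the scene's *true* terrain
rasterized at 0.3 m (`terrain_raster()`), not against an estimated DEM.
This is deliberate: at 15 points/m², IDW gridding noise alone perturbs a
sloped plane by centimetres (the test suite verifies < 0.02 m RMS at 10°,
and a per-point tail past 0.05 m at 30°), so an estimated DEM would test
interpolation noise rather than the correction geometry.
DEM estimation quality is tested separately (plane-recovery RMS, ground
classification recovery, and the flat-scene end-to-end no-op, which is
exact because IDW of a constant is that constant).

## Known limitations

* **Gravity-centre sampling noise.** The centre of gravity estimates the
  trunk position with horizontal sampling noise of roughly
  $R/(2\sqrt{n})$ ≈ 0.06–0.08 m at 15 points/m² (nearly independent of
  crown size, since $n$ grows with $R^2$). The per-point correction
  difference is $\tan i$ times the offset from the *estimated* centre, so
  on steep slopes the $(d/2)\tan i$ bound can be exceeded by a few
  centimetres when the centre lands slightly off the trunk; in the
  package's 20-scene evaluation suite this occurs in a small minority of
  steep-slope scenes, with excesses ≲ 0.03 m. Users comparing against the
  analytic bound should allow for this term, which shrinks with point
  density.
* The correction presumes upright trees; leaning stems displace the
  gravity centre from the base by construction.
* Crowns are consumed as given polygons; segmentation quality bounds
  correction quality, and region-scale application over closed canopies
  with overlapping crowns is out of scope.
* LAS/LAZ input needs an external conversion to xyz text; no LAS backend
  is bundled. The TIFF raster writer stores rescaled 32-bit samples with a
  world file and JSON sidecar rather than full GeoTIFF tags.

## Problem sizes used by the test-suite

Module tests use 10–40 m scenes at the full 15 points/m² density (roughly
1,500–24,000 returns), a 20-scene evaluation suite spanning slopes 10–40°
and crowns 3–10 m, a 21-scene slope sweep (0–40°, fixed 8 m crown) for the
exceedance-proportion regression, and 41 synthetic plots for the Lorey
model recovery — the plot count of the field campaign the method was
designed around.
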