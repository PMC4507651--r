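# canoheight

Terrain correction of LiDAR-derived forest canopy height.

## The problem

Forest inventory from airborne LiDAR starts with normalized canopy
heights: each return's elevation minus the bare-earth DEM directly under
it. On sloping ground this per-point subtraction distorts trees. A crown
return a horizontal distance *c* upslope of the trunk is depressed by
*c* tan *i* (slope angle *i*), a downslope return is elevated by the same
geometry, and the error reaches

```
(d/2) tan(i)
```

at the edge of a crown of diameter *d* — metres on the steep slopes where
much subtropical and montane forest grows. The distortion moves detected
treetops downslope, reshapes segmented crowns and biases every
height-derived stand metric.

`canoheight` corrects this per tree instead of per point. Vegetation
returns are grouped by crown polygon; each group's trunk position is
estimated as the height-weighted planimetric centre of gravity

```
x_ig = sum_j x_ij * w_ij / sum_j w_ij ,   w_ij = z_ij - mean_j(A_ij)
```

(`A_ij` = DEM elevation under point *j*); the tree-base elevation `z_ig`
is the DEM at that centre; and every return of the group is renormalized
as `z_ij - z_ig`. Within a crown the correction is a rigid vertical shift,
so crown morphology is preserved exactly.

Around the core correction the package provides the full working
pipeline: a synthetic LiDAR scene simulator with known ground truth,
multiscale-curvature ground classification, IDW DEM/DSM/CHM gridding,
local-maxima + marker-watershed tree extraction, plot-level
height-difference statistics, and basal-area-weighted (Lorey's) stand
height regression on height percentiles with K-fold forward-stepwise
selection. I/O covers xyz text point clouds, ESRI ASCII and TIFF rasters,
and GeoJSON crown polygons. A thin command-line front end is installed at
`inst/cli/canoheight`.

## Worked example

A 12 m tree with a 6 m crown on a uniform 30° slope, simulated at
15 returns/m², then classified, gridded and corrected:

```r
library(canoheight)

sp <- scene_spec(extent = c(20, 20), slope_deg = 30,
                 trees = list(tree_spec(c(10, 10), height = 12,
                                        crown_diameter = 6)),
                 seed = 42)
sc <- sample_scene(sp)

cl  <- classify_ground(sc$cloud)                  # MCC ground filter
dem <- build_dem(cl, params = idw_params(max_radius = 5))
cc  <- correct_scene(cl, sc$truth$crowns, dem)    # per-tree correction
cc
#> <canopy_correction> 1 tree(s), 415 corrected points, 0 gap point(s), 0 removed
#>   corrected - conventional: [-1.505, 2.154] m, mean |d| 1.159 m

p <- cc$points[!is.na(cc$points$corrected), ]
c(conventional_max = max(p$conventional),
  corrected_max    = max(p$corrected),
  true_height      = sc$truth$trees$height)
#> conventional_max    corrected_max      true_height
#>         13.45345         12.33851         12.00000
```

The conventional maximum overstates the tree by 1.45 m (a downslope crown
edge is elevated by up to 3 tan 30° ≈ 1.73 m); the corrected maximum is
within 0.34 m, the residual coming from DEM interpolation across the
occluded crown footprint. The per-point differences span roughly
±(d/2) tan *i*, and their threshold statistics are the plot-level summary
used to relate terrain to height error:

```r
difference_stats(p$conventional, p$corrected)
#>     k       p_k   mean_k
#> 1 0.3 0.8867470 1.290006
#> 2 0.5 0.8409639 1.337098
#> 3 0.8 0.7036145 1.471364
#> 4 1.0 0.5879518 1.588492
#> 5 1.2 0.4891566 1.687979
#> 6 1.5 0.2746988 1.928776
```

The analytic error table for typical crown sizes and slopes:

```r
round(max_difference_table(), 2)
#>          slope_deg
#> crown_d_m    5   10   20   30   40   50
#>        3  0.13 0.26 0.55 0.87 1.26 1.79
#>        5  0.22 0.44 0.91 1.44 2.10 2.98
#>        10 0.44 0.88 1.82 2.89 4.20 5.96
#>        15 0.66 1.32 2.73 4.33 6.29 8.94
```

See `vignettes/terrain-correction.Rmd` for the model, parameter and
design discussion, and what the synthetic scenes do and do not emulate.

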