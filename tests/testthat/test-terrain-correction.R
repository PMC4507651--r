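square_crown <- function(id, x0, y0, s) {
  m <- rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s))
  attr(m, "hole") <- FALSE
  list(id = id, rings = list(m))
}

test_that("grouping assigns by containment with lowest-id tie-break", {
  pc <- point_cloud(x = c(1, 2, 3, 9, 9.5, 1.5, 2.5, 8),
                    y = c(1, 2, 3, 9, 9.0, 2.5, 1.5, 1),
                    z = rep(5, 8), class = "vegetation")
  crowns <- crown_set(list(square_crown(1, 0, 0, 4)))
  gb <- group_by_crown(pc, crowns)
  expect_equal(length(gb$groups[[1]]$members), 5L)
  expect_equal(sort(gb$gap), c(4L, 5L, 8L))
  # overlapping crowns: shared point goes to the lowest id
  crowns2 <- crown_set(list(square_crown(2, 1.5, 1.5, 3),
                            square_crown(1, 0, 0, 4)))
  gb2 <- group_by_crown(pc, crowns2)
  in1 <- gb2$groups[[which(crown_ids(crowns2) == 1)]]$members
  expect_true(all(c(1L, 2L, 3L) %in% in1))
  expect_error(group_by_crown(pc, crown_set(list())), "empty")
})

test_that("gravity centre follows the height-weighted mean of the group", {
  dem0 <- raster_grid(matrix(0, 30, 30), origin = c(-2, -2), cell = 0.5)
  # single point
  pc1 <- point_cloud(2, 3, 4, class = "vegetation")
  expect_equal(gravity_centre(pc1, 1L, dem0), c(2, 3))
  # symmetric pair with equal heights centres at the midpoint
  pc2 <- point_cloud(c(-1, 1), c(0, 0), c(6, 6), class = "vegetation")
  dems <- raster_grid(matrix(0, 30, 30), origin = c(-5, -5), cell = 0.5)
  expect_equal(gravity_centre(pc2, 1:2, dems)[1], 0)
  # direct evaluation: x = (0,2,4), weights (1,1,2) -> 2.5
  pc3 <- point_cloud(c(0, 2, 4), c(1, 1, 1), c(1, 1, 2), class = "vegetation")
  expect_equal(gravity_centre(pc3, 1:3, dem0)[1], 2.5)
  # all points below the mean ground elevation is degenerate
  dem5 <- raster_grid(matrix(5, 30, 30), origin = c(-2, -2), cell = 0.5)
  expect_error(gravity_centre(pc3, 1:3, dem5), "degenerate")
})

test_that("correction is a rigid vertical shift per group", {
  sc <- scene_slope30()
  cl <- apply_truth_classes(sc$cloud, sc$truth)
  dem <- terrain_raster(sc$spec)
  gb <- group_by_crown(cl, sc$truth$crowns)
  g <- correct_group(cl, gb$groups[[1]], dem)
  zs <- cl$z[g$members]
  expect_equal(max(g$corrected_heights) - min(g$corrected_heights),
               max(zs) - min(zs))
  expect_equal(g$corrected_heights, zs - g$base_elevation)
  # flat DEM at zero: corrected equals raw z
  demf <- raster_grid(matrix(0, 80, 80), origin = c(0, 0), cell = 0.3)
  gf <- correct_group(cl, gb$groups[[1]], demf)
  expect_equal(gf$corrected_heights, zs)
})

test_that("flat terrain makes the correction a no-op", {
  sc <- scene_flat()
  cl <- apply_truth_classes(sc$cloud, sc$truth)
  dem <- terrain_raster(sc$spec)
  cc <- correct_scene(cl, sc$truth$crowns, dem)
  d <- cc$points$corrected - cc$points$conventional
  expect_lt(max(abs(d), na.rm = TRUE), 1e-6)
})

test_that("signs alternate across the trunk along the slope direction", {
  sc <- scene_slope30()
  cl <- apply_truth_classes(sc$cloud, sc$truth)
  dem <- terrain_raster(sc$spec)
  cc <- correct_scene(cl, sc$truth$crowns, dem)
  p <- cc$points[!is.na(cc$points$crown_id), ]
  u <- upslope_offset(sc$spec, cl$x[p$index], cl$y[p$index],
                      unlist(cc$trees[1, c("x_ig", "y_ig")]))
  # before-minus-after difference: conventional heights are elevated
  # downslope of the trunk and depressed upslope
  d <- p$conventional - p$corrected
  expect_true(all(d[u < -0.05] > 0))
  expect_true(all(d[u > 0.05] < 0))
})

test_that("correcting a steep single tree beats conventional apex height", {
  sc <- scene_slope30()
  cl <- apply_truth_classes(sc$cloud, sc$truth)
  dem <- terrain_raster(sc$spec)
  cc <- correct_scene(cl, sc$truth$crowns, dem)
  h_true <- sc$truth$trees$height[1]
  err_corr <- abs(cc$trees$max_corrected - h_true)
  conv <- cc$points$conventional[!is.na(cc$points$crown_id)]
  err_conv <- abs(max(conv) - h_true)
  expect_lt(err_corr, 0.15)
  expect_gt(err_conv, err_corr)
})

test_that("gap handling follows the vegetation threshold", {
  sc <- scene_flat()
  cl <- apply_truth_classes(sc$cloud, sc$truth)
  # mislabel everything vegetation so ground becomes gap candidates
  cl$class <- "vegetation"
  dem <- terrain_raster(sc$spec)
  cc <- correct_scene(cl, sc$truth$crowns, dem)
  # all retained gap points are above the threshold
  expect_true(all(cc$points$conventional[is.na(cc$points$crown_id)] > 1.8))
  expect_gt(length(cc$removed), 0)
  cc2 <- correct_scene(cl, sc$truth$crowns, dem,
                       correction_config(gap_removal = FALSE))
  expect_equal(length(cc2$removed), 0L)
  expect_error(correct_scene(cl, crown_set(list()), dem), "empty")
})
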