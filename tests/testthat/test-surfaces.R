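test_that("IDW reduces to the constant, the coincident point and symmetry", {
  g <- idw_interpolate(c(1, 2, 3), c(1, 2, 3), c(7, 7, 7),
                       origin = c(0, 0), cell = 1, nrow = 4, ncol = 4,
                       params = idw_params(max_radius = 10))
  expect_equal(g$values, matrix(7, 4, 4), tolerance = 1e-12)
  # single point: its cell takes its z, far cells are nodata
  g1 <- idw_interpolate(2, 2, 5, origin = c(0, 0), cell = 1,
                        nrow = 8, ncol = 8, params = idw_params(max_radius = 2))
  expect_equal(g1$values[3, 3], 5)
  expect_true(is.na(g1$values[8, 8]))
  # two points equidistant from a cell average exactly
  g2 <- idw_interpolate(c(0, 2), c(1, 1), c(0, 10), origin = c(0, 0),
                        cell = 1, nrow = 3, ncol = 3,
                        params = idw_params(max_radius = 5))
  expect_equal(g2$values[2, 2], 5)
  # output bounded by contributing points
  set.seed(1)
  gb <- idw_interpolate(runif(50, 0, 5), runif(50, 0, 5), runif(50, 2, 9),
                        origin = c(0, 0), cell = 0.5, nrow = 11, ncol = 11,
                        params = idw_params(max_radius = 10))
  expect_true(all(gb$values >= 2 & gb$values <= 9))
  expect_error(idw_interpolate(numeric(0), numeric(0), numeric(0),
                               c(0, 0), 1, 2, 2), "no input")
})

test_that("a DEM from noiseless sloped ground reproduces the plane", {
  sp <- scene_spec(extent = c(15, 15), slope_deg = 10, seed = 8)
  sc <- sample_scene(sp)
  cl <- apply_truth_classes(sc$cloud, sc$truth)
  dem <- build_dem(cl)
  # compare interior cells to the closed-form plane
  xs <- canoheight:::.grid_x(dem); ys <- canoheight:::.grid_y(dem)
  keep_x <- xs > 1 & xs < 14; keep_y <- ys > 1 & ys < 14
  err <- dem$values[keep_y, keep_x] -
    outer(ys[keep_y], xs[keep_x], function(y, x) terrain_elevation(sp, x, y))
  expect_lt(sqrt(mean(err^2)), 0.02)
  # flat ground is exact
  spf <- scene_spec(extent = c(10, 10), seed = 2)
  scf <- sample_scene(spf)
  demf <- build_dem(apply_truth_classes(scf$cloud, scf$truth))
  expect_lt(max(abs(demf$values), na.rm = TRUE), 1e-12)
  # cell argument is honoured
  dem5 <- build_dem(cl, cell = 0.5)
  expect_equal(dem5$cell, 0.5)
  expect_error(build_dem(scf$cloud), "no ground")
})

test_that("conventional normalization is exactly invertible and plane-true", {
  sc <- scene_slope30()
  cl <- apply_truth_classes(sc$cloud, sc$truth)
  dem <- build_dem(cl, params = idw_params(max_radius = 5))
  h <- conventional_normalize(cl, dem)
  expect_equal(h + sample_surface(dem, cl$x, cl$y), cl$z)
  g <- sc$truth$points$is_ground
  # IDW gridding noise grows with tan(slope); at 30 degrees the ground
  # heights stay near zero in RMS with a small tail
  expect_lt(sqrt(mean(h[g]^2)), 0.05)
  expect_lt(max(abs(h[g])), 0.2)
  # flat scene: tree apex height recovered
  flat <- scene_flat()
  clf <- apply_truth_classes(flat$cloud, flat$truth)
  demf <- build_dem(clf, params = idw_params(max_radius = 5))
  hf <- conventional_normalize(clf, demf)
  t1 <- flat$truth$points$tree_id == 1L
  expect_equal(max(hf[t1]), flat$truth$trees$height[1], tolerance = 1e-6)
})

test_that("CHM gridding matches for identical heights and flags negatives", {
  sc <- scene_flat()
  veg <- !sc$truth$points$is_ground
  x <- sc$cloud$x[veg]; y <- sc$cloud$y[veg]
  h <- sc$truth$points$true_height[veg]
  c1 <- build_chm(x, y, h)
  c2 <- build_chm(x, y, h)
  expect_equal(c1$values, c2$values)
  cneg <- build_chm(x, y, h - 20)
  expect_lt(max(cneg$values, na.rm = TRUE), 0)
  expect_error(build_chm(numeric(0), numeric(0), numeric(0)), "no vegetation")
})
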