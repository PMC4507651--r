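gauss_bump <- function(nr = 40, nc = 40, cell = 0.3, centres, heights,
                       sigma = 1.2) {
  xs <- (0:(nc - 1)) * cell; ys <- (0:(nr - 1)) * cell
  v <- matrix(0, nr, nc)
  for (k in seq_along(heights)) {
    v <- v + heights[k] *
      outer(ys, xs, function(y, x)
        exp(-((x - centres[[k]][1])^2 + (y - centres[[k]][2])^2) /
              (2 * sigma^2)))
  }
  raster_grid(v, origin = c(0, 0), cell = cell)
}

test_that("local maxima detection finds bumps and ignores plateaus", {
  chm <- gauss_bump(centres = list(c(6, 6)), heights = 10)
  ap <- detect_apices(chm)
  expect_equal(nrow(ap), 1L)
  expect_lt(abs(ap$x - 6) + abs(ap$y - 6), 0.31)
  expect_equal(ap$height, max(chm$values))
  # flat CHM: no strict maximum anywhere
  flat <- raster_grid(matrix(5, 30, 30), cell = 0.3)
  expect_equal(nrow(detect_apices(flat)), 0L)
  # two bumps separated by more than the window
  chm2 <- gauss_bump(centres = list(c(3.5, 3.5), c(9, 9)), heights = c(8, 11))
  expect_equal(nrow(detect_apices(chm2)), 2L)
  expect_error(detect_apices(gauss_bump(nr = 5, nc = 5, centres = list(c(1, 1)),
                                        heights = 5), window = 6), "window")
})

test_that("apex count is monotone non-increasing in window size", {
  sc <- scene_flat()
  veg <- !sc$truth$points$is_ground
  chm <- build_chm(sc$cloud$x[veg], sc$cloud$y[veg],
                   sc$truth$points$true_height[veg])
  counts <- vapply(c(1, 2, 3, 5, 8), function(w)
    nrow(detect_apices(chm, window = w)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("watershed labels partition the height mask around the apices", {
  chm <- gauss_bump(centres = list(c(3.5, 3.5), c(9, 9)), heights = c(8, 11))
  ap <- detect_apices(chm)
  lab <- segment_crowns_watershed(chm, ap)
  m <- chm$values >= 1.8
  expect_true(all(!is.na(lab$values[m])))    # mask fully labelled
  expect_true(all(is.na(lab$values[!m])))    # nothing outside the mask
  # each apex sits in its own region
  expect_equal(lab$values[cbind(ap$row, ap$col)], seq_len(nrow(ap)))
  expect_equal(sort(unique(na.omit(c(lab$values)))), 1:2)
  expect_error(segment_crowns_watershed(chm, ap[0, ]), "apex")
})

test_that("a five-tree scene is recovered to within one detection", {
  sp <- scene_spec(extent = c(40, 40), slope_deg = 0,
                   trees = list(tree_spec(c(8, 8), 12, 6),
                                tree_spec(c(25, 10), 15, 7),
                                tree_spec(c(12, 25), 10, 5),
                                tree_spec(c(30, 30), 14, 6),
                                tree_spec(c(20, 18), 11, 5)),
                   seed = 12)
  sc <- sample_scene(sp)
  veg <- !sc$truth$points$is_ground
  chm <- build_chm(sc$cloud$x[veg], sc$cloud$y[veg],
                   sc$truth$points$true_height[veg],
                   params = idw_params(max_radius = 1))
  ap <- detect_apices(chm, window = 3)
  expect_lte(abs(nrow(ap) - 5L), 1L)
  cmp <- compare_extractions(ap, data.frame(x = sc$truth$trees$x,
                                            y = sc$truth$trees$y))
  expect_gte(nrow(cmp$matched), 4L)
  expect_lt(cmp$mean_dist, 0.3 * sqrt(2))   # within one cell on average
})

test_that("matching is exact for identical lists and robust to empties", {
  a <- data.frame(x = c(1, 5, 9), y = c(2, 5, 1))
  cmp <- compare_extractions(a, a)
  expect_equal(nrow(cmp$matched), 3L)
  expect_equal(cmp$max_dist, 0)
  cmp0 <- compare_extractions(a, a[0, ])
  expect_equal(nrow(cmp0$matched), 0L)
  expect_equal(cmp0$unmatched_a, 1:3)
})

test_that("flat-scene detections agree between CHM I and CHM II", {
  sc <- scene_flat()
  cl <- apply_truth_classes(sc$cloud, sc$truth)
  dem <- terrain_raster(sc$spec)
  cc <- correct_scene(cl, sc$truth$crowns, dem)
  p <- cc$points[!is.na(cc$points$crown_id), ]
  geo <- canoheight:::.bbox_grid(cl$x[p$index], cl$y[p$index], 0.3)
  chm1 <- build_chm(cl$x[p$index], cl$y[p$index], p$conventional,
                    geometry = geo)
  chm2 <- build_chm(cl$x[p$index], cl$y[p$index], p$corrected,
                    geometry = geo)
  a1 <- detect_apices(chm1)
  a2 <- detect_apices(chm2)
  expect_equal(a1, a2, tolerance = 1e-9)
})
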