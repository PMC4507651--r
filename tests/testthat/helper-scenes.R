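# Shared synthetic scenes, built once per test file.
.scene_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .scene_cache)) assign(key, force(expr), .scene_cache)
  get(key, .scene_cache)
}

# one 12 m tree (6 m crown) centred on a noiseless 30-degree slope
scene_slope30 <- function() cached("slope30", {
  sp <- scene_spec(extent = c(20, 20), slope_deg = 30,
                   trees = list(tree_spec(c(10, 10), 12, 6)), seed = 42)
  c(list(spec = sp), sample_scene(sp))
})

# flat noiseless scene with two separated trees
scene_flat <- function() cached("flat", {
  sp <- scene_spec(extent = c(24, 24), slope_deg = 0,
                   trees = list(tree_spec(c(7, 7), 10, 5),
                                tree_spec(c(17, 17), 13, 6)),
                   seed = 7)
  c(list(spec = sp), sample_scene(sp))
})

# upslope-signed horizontal offsets of points from a tree base
upslope_offset <- function(spec, x, y, base_xy) {
  a <- spec$aspect_deg * pi / 180
  (x - base_xy[1]) * sin(a) + (y - base_xy[2]) * cos(a)
}

expect_silent_file <- function(path) {
  expect_true(file.exists(path))
  expect_gt(file.info(path)$size, 0)
}
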