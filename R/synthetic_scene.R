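#' Parametric tree for synthetic scenes
#'
#' @param base_xy length-2 numeric, trunk base position (m).
#' @param height total tree height above its base (m).
#' @param crown_diameter crown diameter (m).
#' @param crown_shape `"spheroid"` (half-spheroid cap between crown base and
#'   apex) or `"cone"`.
#' @param crown_base_height height of the crown base above the tree base (m);
#'   must satisfy `0 <= crown_base_height < height`.
#' @return An object of class `tree_spec`.
#' @export
tree_spec <- function(base_xy, height, crown_diameter,
                      crown_shape = c("spheroid", "cone"),
                      crown_base_height = 2) {
  crown_shape <- match.arg(crown_shape)
  if (crown_diameter <= 0) stop("crown_diameter must be positive")
  if (crown_base_height < 0 || height <= crown_base_height)
    stop("need height > crown_base_height >= 0")
  structure(list(base_xy = as.numeric(base_xy), height = height,
                 crown_diameter = crown_diameter, crown_shape = crown_shape,
                 crown_base_height = crown_base_height),
            class = "tree_spec")
}

#' Synthetic LiDAR scene description
#'
#' Describes a rectangular scene: planar sloping terrain (optionally with a
#' smooth random roughness field), parametric tree crowns, and a first-return
#' sampling density. Defaults reflect a typical small-footprint forest
#' survey: 15 first returns per square metre and a 0.3 m DEM cell downstream.
#'
#' The roughness field is a seeded mixture of low-frequency cosine waves
#' (wavelengths between one quarter and the full scene width), scaled to the
#' requested standard deviation, so that it is smooth (C-infinity) rather
#' than white noise and curvature-based ground filtering remains meaningful.
#'
#' @param extent length-2 numeric, scene width and depth in metres.
#' @param slope_deg terrain slope angle in degrees (0-55).
#' @param aspect_deg upslope azimuth in degrees; 0 means the +y axis points
#'   upslope, 90 means +x.
#' @param roughness_sd standard deviation of the smooth roughness field (m).
#' @param trees list of [tree_spec()] objects.
#' @param density expected first-return density (points per m^2).
#' @param noise_sd_z Gaussian standard deviation added to every return's z
#'   (m); 0 gives noiseless geometry.
#' @param seed integer seed; scenes with equal specs and seeds are identical.
#' @return An object of class `scene_spec`.
#' @examples
#' sp <- scene_spec(extent = c(20, 20), slope_deg = 30,
#'                  trees = list(tree_spec(c(10, 10), 12, 6)))
#' @export
scene_spec <- function(extent = c(30, 30), slope_deg = 0, aspect_deg = 0,
                       roughness_sd = 0, trees = list(), density = 15,
                       noise_sd_z = 0, seed = 1L) {
  if (density <= 0) stop("density must be positive")
  if (slope_deg < 0 || slope_deg >= 90) stop("slope_deg must be in [0, 90)")
  if (roughness_sd < 0) stop("roughness_sd must be non-negative")
  if (length(extent) != 2L || any(extent <= 0)) stop("invalid extent")
  trees <- lapply(trees, function(t) {
    if (!inherits(t, "tree_spec")) do.call(tree_spec, t) else t
  })
  sp <- structure(list(extent = as.numeric(extent), slope_deg = slope_deg,
                       aspect_deg = aspect_deg, roughness_sd = roughness_sd,
                       trees = trees, density = density,
                       noise_sd_z = noise_sd_z, seed = as.integer(seed)),
                  class = "scene_spec")
  sp$roughness_components <- .roughness_components(sp)
  sp
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %g x %g m, slope %g deg (aspect %g), %d tree(s), %g p/m2, seed %d\n",
              x$extent[1], x$extent[2], x$slope_deg, x$aspect_deg,
              length(x$trees), x$density, x$seed))
  invisible(x)
}

# run expr with a private, seeded RNG stream; restores the caller's RNG
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.roughness_components <- function(spec) {
  if (spec$roughness_sd <= 0) return(NULL)
  W <- max(spec$extent)
  .with_seed(spec$seed + 7919L, {
    m <- 8L
    wavelength <- runif(m, W / 4, W)
    theta <- runif(m, 0, 2 * pi)
    phase <- runif(m, 0, 2 * pi)
    amp <- runif(m, 0.5, 1)
    # each cosine has variance amp^2/2; scale mixture to roughness_sd
    amp <- amp * spec$roughness_sd / sqrt(sum(amp^2) / 2)
    list(fx = cos(theta) / wavelength, fy = sin(theta) / wavelength,
         phase = phase, amp = amp)
  })
}

#' Terrain elevation of a synthetic scene
#'
#' The planar part is `tan(slope) * (distance along the upslope azimuth)`;
#' the smooth roughness field (if any) is added on top. Deterministic given
#' the scene spec.
#'
#' @param spec a [scene_spec()].
#' @param x,y coordinate vectors (m).
#' @return Elevation in metres.
#' @examples
#' sp <- scene_spec(slope_deg = 45)
#' terrain_elevation(sp, 0, 10)  # 10 m: tan(45 deg) * 10
#' @export
terrain_elevation <- function(spec, x, y) {
  stopifnot(inherits(spec, "scene_spec"))
  a <- spec$aspect_deg * pi / 180
  up <- x * sin(a) + y * cos(a)
  z <- tan(spec$slope_deg * pi / 180) * up
  r <- spec$roughness_components
  if (!is.null(r))
    for (m in seq_along(r$amp))
      z <- z + r$amp[m] * cos(2 * pi * (r$fx[m] * x + r$fy[m] * y) + r$phase[m])
  z
}

#' True terrain raster of a synthetic scene
#'
#' Rasterizes [terrain_elevation()] at cell centres covering the scene
#' extent padded by one cell. This is the scene's exact bare-earth surface,
#' used as the reference DEM when evaluating the correction geometry
#' independently of DEM estimation error.
#'
#' @param spec a [scene_spec()].
#' @param cell cell size (m), default 0.3.
#' @return A [raster_grid()].
#' @export
terrain_raster <- function(spec, cell = 0.3) {
  stopifnot(inherits(spec, "scene_spec"))
  xs <- seq(-cell, spec$extent[1] + cell, by = cell)
  ys <- seq(-cell, spec$extent[2] + cell, by = cell)
  v <- outer(ys, xs, function(y, x) terrain_elevation(spec, x, y))
  raster_grid(v, origin = c(xs[1], ys[1]), cell = cell)
}

# upper crown envelope height above the tree base at radial offset r
.crown_envelope <- function(tree, r) {
  R <- tree$crown_diameter / 2
  h <- tree$height; cbh <- tree$crown_base_height
  r <- pmin(r, R)
  if (tree$crown_shape == "spheroid") {
    mid <- (cbh + h) / 2
    mid + (h - cbh) / 2 * sqrt(pmax(0, 1 - (r / R)^2))
  } else {
    cbh + (h - cbh) * (1 - r / R)
  }
}

#' Simulate first-return LiDAR over a synthetic scene
#'
#' Ground returns are Poisson-sampled uniformly over the scene at the scene
#' density and removed inside crown footprints (full canopy occlusion of the
#' ground: first returns under a crown come from the crown surface). Each
#' crown contributes Poisson-sampled returns uniform in plan over its
#' footprint, placed on the upper envelope of the crown solid (terrain
#' independent), plus one deterministic return at the crown apex so that the
#' top of every tree is observed. Where crown footprints overlap, the
#' highest envelope wins and the affected trees are flagged. Gaussian noise
#' of sd `noise_sd_z` is added to all z.
#'
#' @param spec a [scene_spec()].
#' @return A list with elements `cloud` (a [point_cloud()], all returns
#'   first, class `"unclassified"`) and `truth` (list: `trees` data frame
#'   with per-tree true base elevation/height/overlap flag, `points` data
#'   frame with `is_ground`, `tree_id` (0 for ground) and `true_height`
#'   above the owning tree's base, and `crowns`, the true crown polygons).
#' @export
sample_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  W <- spec$extent[1]; H <- spec$extent[2]
  trees <- spec$trees
  nt <- length(trees)
  .with_seed(spec$seed, {
    ng <- rpois(1L, spec$density * W * H)
    gx <- runif(ng, 0, W); gy <- runif(ng, 0, H)
    if (nt > 0L) {
      occl <- rep(FALSE, ng)
      for (t in trees) {
        R <- t$crown_diameter / 2
        occl <- occl | (gx - t$base_xy[1])^2 + (gy - t$base_xy[2])^2 <= R^2
      }
      gx <- gx[!occl]; gy <- gy[!occl]
    }
    gz <- terrain_elevation(spec, gx, gy)

    cx <- cy <- cz <- th <- numeric(0)
    cid <- integer(0)
    overlap <- rep(FALSE, nt)
    if (nt > 0L) {
      base_z <- vapply(trees, function(t)
        terrain_elevation(spec, t$base_xy[1], t$base_xy[2]), 0)
      for (i in seq_len(nt)) {
        t <- trees[[i]]
        R <- t$crown_diameter / 2
        m <- rpois(1L, spec$density * pi * R^2)
        ang <- runif(m, 0, 2 * pi)
        rad <- R * sqrt(runif(m))
        # deterministic apex return
        px <- c(t$base_xy[1] + rad * cos(ang), t$base_xy[1])
        py <- c(t$base_xy[2] + rad * sin(ang), t$base_xy[2])
        rad <- c(rad, 0)
        pz <- base_z[i] + .crown_envelope(t, rad)
        own <- rep(i, length(px))
        hgt <- pz - base_z[i]
        # overlap resolution: another crown's envelope may be higher
        for (j in seq_len(nt)[-i]) {
          tj <- trees[[j]]
          rj <- sqrt((px - tj$base_xy[1])^2 + (py - tj$base_xy[2])^2)
          inside <- rj <= tj$crown_diameter / 2
          if (any(inside)) {
            zj <- base_z[j] + .crown_envelope(tj, rj[inside])
            take <- zj > pz[inside]
            if (any(take)) {
              overlap[c(i, j)] <- TRUE
              idx <- which(inside)[take]
              pz[idx] <- zj[take]
              own[idx] <- j
              hgt[idx] <- pz[idx] - base_z[j]
            }
          }
        }
        # a crown edge cut into the slope: the terrain is the first return
        ter <- terrain_elevation(spec, px, py)
        buried <- ter > pz
        pz[buried] <- ter[buried]
        own[buried] <- 0L
        hgt[buried] <- 0
        cx <- c(cx, px); cy <- c(cy, py); cz <- c(cz, pz)
        cid <- c(cid, own); th <- c(th, hgt)
      }
    }
    x <- c(gx, cx); y <- c(gy, cy); z <- c(gz, cz)
    if (spec$noise_sd_z > 0) z <- z + rnorm(length(z), 0, spec$noise_sd_z)
    is_ground <- c(rep(TRUE, length(gx)), cid == 0L)
    tree_id <- c(rep(0L, length(gx)), cid)
    true_height <- c(rep(0, length(gx)), th)
    cloud <- point_cloud(x, y, z, return_number = 1L, class = "unclassified")
    trees_df <- if (nt > 0L)
      data.frame(id = seq_len(nt),
                 x = vapply(trees, function(t) t$base_xy[1], 0),
                 y = vapply(trees, function(t) t$base_xy[2], 0),
                 height = vapply(trees, function(t) t$height, 0),
                 crown_diameter = vapply(trees, function(t) t$crown_diameter, 0),
                 base_elevation = vapply(trees, function(t)
                   terrain_elevation(spec, t$base_xy[1], t$base_xy[2]), 0),
                 overlap = overlap)
    else data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    height = numeric(0), crown_diameter = numeric(0),
                    base_elevation = numeric(0), overlap = logical(0))
    list(cloud = cloud,
         truth = list(trees = trees_df,
                      points = data.frame(is_ground = is_ground,
                                          tree_id = tree_id,
                                          true_height = true_height),
                      crowns = truth_crown_polygons(spec)))
  })
}

#' True crown polygons of a synthetic scene
#'
#' Polygonized circles (48 vertices) of each tree's crown footprint, with
#' ids matching the tree order. Stands in for an image-segmentation product
#' when testing the correction pipeline.
#'
#' @param spec a [scene_spec()].
#' @param n_vertices vertices per circle (>= 32).
#' @return A [crown_set()].
#' @export
truth_crown_polygons <- function(spec, n_vertices = 48L) {
  stopifnot(inherits(spec, "scene_spec"))
  if (n_vertices < 32L) stop("n_vertices must be >= 32")
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  polys <- lapply(seq_along(spec$trees), function(i) {
    t <- spec$trees[[i]]
    R <- t$crown_diameter / 2
    ring <- cbind(t$base_xy[1] + R * cos(ang), t$base_xy[2] + R * sin(ang))
    attr(ring, "hole") <- FALSE
    list(id = i, rings = list(ring))
  })
  crown_set(polys)
}

#' Copy truth ground flags onto a cloud's class labels
#'
#' Convenience for evaluating downstream stages independently of the ground
#' filter: labels every truth ground return `"ground"` and everything else
#' `"vegetation"`.
#'
#' @param cloud the `cloud` element of [sample_scene()] output.
#' @param truth the matching `truth` element.
#' @return The relabelled [point_cloud()].
#' @export
apply_truth_classes <- function(cloud, truth) {
  stopifnot(inherits(cloud, "point_cloud"))
  cloud$class <- ifelse(truth$points$is_ground, "ground", "vegetation")
  cloud
}
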