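#' Correction configuration
#'
#' @param vegetation_threshold height (m) separating canopy from shrub and
#'   ground clutter; echoes higher than 1.8 m above ground are conventionally
#'   treated as vegetation, and gap returns at or below the threshold are
#'   removed when `gap_removal` is on.
#' @param gap_removal drop forest-gap returns (points inside no crown
#'   polygon) whose conventional height is at or below the threshold.
#' @return An object of class `correction_config`.
#' @export
correction_config <- function(vegetation_threshold = 1.8, gap_removal = TRUE) {
  if (vegetation_threshold < 0) stop("vegetation_threshold must be >= 0")
  structure(list(vegetation_threshold = vegetation_threshold,
                 gap_removal = isTRUE(gap_removal)),
            class = "correction_config")
}

#' Group first-return vegetation points by crown polygon
#'
#' Assigns every first-return, non-ground point to the crown polygon that
#' contains it. Points inside no polygon are forest-gap points. A point on a
#' shared boundary (or inside several overlapping polygons) goes to the
#' polygon with the lowest id.
#'
#' @param cloud a [point_cloud()].
#' @param crowns a [crown_set()].
#' @return A list with `groups` (list of `tree_group` objects carrying
#'   `crown_id` and the member point indices into `cloud`; empty groups are
#'   kept and flagged) and `gap` (indices of unassigned candidate points).
#' @export
group_by_crown <- function(cloud, crowns) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(crowns, "crown_set"))
  if (length(crowns$polygons) == 0L) stop("crown set is empty")
  cand <- which(cloud$return_number == 1L & cloud$class != "ground")
  assigned <- rep(NA_integer_, length(cand))
  ids <- crown_ids(crowns)
  ord <- order(ids)
  for (pi in ord) {
    open <- is.na(assigned)
    if (!any(open)) break
    s <- .crown_contains(crowns$polygons[[pi]], cloud$x[cand[open]],
                         cloud$y[cand[open]])
    assigned[which(open)[s > 0L]] <- pi
  }
  groups <- lapply(seq_along(crowns$polygons), function(pi) {
    structure(list(crown_id = ids[pi], members = cand[which(assigned == pi)]),
              class = "tree_group")
  })
  list(groups = groups, gap = cand[is.na(assigned)])
}

#' Height-weighted centre of gravity of a crown's returns
#'
#' The planimetric centre of gravity of point group i is the weighted mean
#' of the member coordinates with weights
#' `w_j = z_j - mean(A)`, where `A` are the DEM elevations under the group's
#' points; for an upright tree this centre falls under the crown apex, i.e.
#' over the tree base. Negative weights (points below the group's mean
#' ground elevation, pathological after vegetation thresholding) are clamped
#' to zero so the centre stays a convex combination of member positions.
#'
#' @param cloud a [point_cloud()].
#' @param members integer indices of the group's points.
#' @param dem a [raster_grid()].
#' @return Length-2 numeric `(x, y)` of the gravity centre.
#' @export
gravity_centre <- function(cloud, members, dem) {
  if (length(members) < 1L) stop("empty group")
  A <- sample_surface(dem, cloud$x[members], cloud$y[members])
  w <- pmax(cloud$z[members] - mean(A), 0)
  sw <- sum(w)
  if (sw <= 0)
    stop("degenerate group: no point above the mean ground elevation")
  c(sum(cloud$x[members] * w), sum(cloud$y[members] * w)) / sw
}

#' Correct one crown group against its base elevation
#'
#' Samples the DEM (bilinearly) at the group's gravity centre to obtain the
#' tree-base elevation `z_ig`, and renormalizes every member as
#' `corrected_j = z_j - z_ig`. The corrected heights are a rigid vertical
#' shift of the raw elevations, so all intra-crown structure (pairwise
#' height differences) is preserved exactly.
#'
#' @param cloud a [point_cloud()].
#' @param group a `tree_group` from [group_by_crown()].
#' @param dem a [raster_grid()].
#' @return The group with `gravity_xy`, `base_elevation` and
#'   `corrected_heights` filled in.
#' @export
correct_group <- function(cloud, group, dem) {
  stopifnot(inherits(group, "tree_group"))
  g <- gravity_centre(cloud, group$members, dem)
  zig <- sample_surface(dem, g[1], g[2])
  group$gravity_xy <- g
  group$base_elevation <- zig
  group$corrected_heights <- cloud$z[group$members] - zig
  group
}

#' Per-tree terrain correction of a normalized point cloud
#'
#' The full correction: first-return vegetation points are grouped by crown
#' polygon, each group's base elevation is taken from the DEM at its
#' height-weighted gravity centre, and the group's returns are renormalized
#' against that single elevation. Forest-gap points (inside no crown) keep
#' their conventional heights; when `config$gap_removal` is on, gap points
#' whose conventional height is at or below `config$vegetation_threshold`
#' are dropped from the result. Degenerate groups (no positive weight) are
#' skipped with a warning; the call fails only if every group is degenerate.
#'
#' @param cloud a [point_cloud()].
#' @param crowns a [crown_set()].
#' @param dem a [raster_grid()] covering the cloud.
#' @param config a [correction_config()].
#' @return An object of class `canopy_correction`: a list with `points`
#'   (data frame: cloud index, crown id (NA for gap points), `conventional`
#'   and `corrected` heights), `trees` (per-tree table: crown id, gravity
#'   centre, base elevation, member count, maximum corrected height,
#'   low-confidence flag for groups of fewer than 3 points), `gap`
#'   (indices of retained gap points) and `removed` (indices dropped by gap
#'   removal).
#' @export
correct_scene <- function(cloud, crowns, dem, config = correction_config()) {
  stopifnot(inherits(cloud, "point_cloud"))
  gb <- group_by_crown(cloud, crowns)
  conv <- conventional_normalize(cloud, dem)
  groups <- list()
  degenerate <- 0L
  for (g in gb$groups) {
    if (length(g$members) == 0L) next
    cg <- tryCatch(correct_group(cloud, g, dem), error = function(e) e)
    if (inherits(cg, "error")) {
      degenerate <- degenerate + 1L
      warning("crown ", g$crown_id, " skipped: ", conditionMessage(cg))
      next
    }
    groups[[length(groups) + 1L]] <- cg
  }
  if (length(groups) == 0L)
    stop("no crown group could be corrected",
         if (degenerate > 0L) " (all groups degenerate)" else "")
  idx <- unlist(lapply(groups, `[[`, "members"))
  corr <- unlist(lapply(groups, `[[`, "corrected_heights"))
  cid <- unlist(lapply(groups, function(g) rep(g$crown_id, length(g$members))))
  gap <- gb$gap
  removed <- integer(0)
  if (config$gap_removal && length(gap)) {
    low <- conv[gap] <= config$vegetation_threshold
    removed <- gap[low]
    gap <- gap[!low]
  }
  pts <- rbind(
    data.frame(index = idx, crown_id = cid, conventional = conv[idx],
               corrected = corr),
    if (length(gap)) data.frame(index = gap, crown_id = NA,
                                conventional = conv[gap],
                                corrected = NA_real_))
  trees <- data.frame(
    crown_id = unlist(lapply(groups, `[[`, "crown_id")),
    x_ig = vapply(groups, function(g) g$gravity_xy[1], 0),
    y_ig = vapply(groups, function(g) g$gravity_xy[2], 0),
    z_ig = vapply(groups, `[[`, 0, "base_elevation"),
    n = vapply(groups, function(g) length(g$members), 0L),
    max_corrected = vapply(groups, function(g) max(g$corrected_heights), 0))
  trees$low_confidence <- trees$n < 3L
  structure(list(points = pts, trees = trees, groups = groups, gap = gap,
                 removed = removed, config = config),
            class = "canopy_correction")
}

#' @export
print.canopy_correction <- function(x, ...) {
  cat(sprintf("<canopy_correction> %d tree(s), %d corrected points, %d gap point(s), %d removed\n",
              nrow(x$trees), sum(!is.na(x$points$crown_id)), length(x$gap),
              length(x$removed)))
  d <- x$points$corrected - x$points$conventional
  d <- d[!is.na(d)]
  cat(sprintf("  corrected - conventional: [%.3f, %.3f] m, mean |d| %.3f m\n",
              min(d), max(d), mean(abs(d))))
  invisible(x)
}

#' @export
summary.canopy_correction <- function(object, ...) {
  d <- object$points$corrected - object$points$conventional
  out <- list(trees = object$trees,
              n_points = sum(!is.na(object$points$crown_id)),
              n_gap = length(object$gap), n_removed = length(object$removed),
              difference = summary(d[!is.na(d)]),
              stats = difference_stats(
                object$points$conventional[!is.na(object$points$corrected)],
                object$points$corrected[!is.na(object$points$corrected)]))
  class(out) <- "summary.canopy_correction"
  out
}

#' @export
print.summary.canopy_correction <- function(x, ...) {
  cat(sprintf("Per-tree terrain correction: %d tree(s), %d corrected points\n",
              nrow(x$trees), x$n_points))
  print(x$trees, row.names = FALSE)
  cat("\nCorrected - conventional height differences (m):\n")
  print(x$difference)
  cat("\nThreshold statistics:\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Plot corrected against conventional heights
#'
#' One point per corrected return; the diagonal marks the flat-terrain
#' no-op. The vertical scatter around the diagonal is the terrain-induced
#' bias removed by the correction.
#'
#' @param x a `canopy_correction`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.canopy_correction <- function(x, ...) {
  p <- x$points[!is.na(x$points$corrected), ]
  graphics::plot(p$conventional, p$corrected,
                 xlab = "conventional height (m)",
                 ylab = "corrected height (m)",
                 pch = 16, cex = 0.4, col = "#00000055", ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}
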