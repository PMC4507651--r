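#' Inverse-distance-weighting parameters
#'
#' Conventional defaults: power 2, the 12 nearest points, search radius 10
#' cells (set at interpolation time when `max_radius` is `NULL`). Note that
#' under fully occluding canopy the search radius must reach past the crown
#' footprint to the nearest ground returns, so pipelines with large crowns
#' should widen `max_radius` accordingly.
#'
#' @param power weighting exponent (> 0).
#' @param neighbors maximum number of nearest points used per cell (>= 1).
#' @param max_radius search radius in metres, or `NULL` for 10 x cell.
#' @return An object of class `idw_params`.
#' @export
idw_params <- function(power = 2, neighbors = 12L, max_radius = NULL) {
  if (power <= 0) stop("power must be positive")
  if (neighbors < 1L) stop("neighbors must be >= 1")
  structure(list(power = power, neighbors = as.integer(neighbors),
                 max_radius = max_radius), class = "idw_params")
}

#' IDW interpolation of scattered points onto a grid
#'
#' Each cell takes the inverse-distance weighted mean of up to
#' `params$neighbors` nearest points within `params$max_radius`; a cell
#' coincident with a point takes that point's value; cells with no point in
#' range are nodata. Output values are bounded by the contributing points.
#'
#' @param x,y,z point coordinates and values.
#' @param origin lower-left cell centre of the target grid.
#' @param cell cell size (m).
#' @param nrow,ncol grid shape.
#' @param params an [idw_params()].
#' @return A [raster_grid()].
#' @export
idw_interpolate <- function(x, y, z, origin, cell, nrow, ncol,
                            params = idw_params()) {
  if (length(x) == 0L) stop("no input points")
  maxr <- params$max_radius %||% (10 * cell)
  v <- cpp_idw_grid(as.numeric(x), as.numeric(y), as.numeric(z),
                    origin[1], origin[2], cell, as.integer(nrow),
                    as.integer(ncol), params$power, params$neighbors, maxr)
  if (!any(is.finite(v)))
    stop("no grid cell has a point within max_radius")
  raster_grid(v, origin = origin, cell = cell)
}

# bounding-box grid geometry padded by one cell
.bbox_grid <- function(x, y, cell) {
  ox <- min(x) - cell; oy <- min(y) - cell
  list(origin = c(ox, oy),
       ncol = floor((max(x) + cell - ox) / cell) + 1L,
       nrow = floor((max(y) + cell - oy) / cell) + 1L)
}

#' Build a DEM from ground-classified returns
#'
#' IDW interpolation of the ground returns onto a grid covering the cloud's
#' bounding box padded by one cell.
#'
#' @param cloud a [point_cloud()] with ground-labelled points.
#' @param cell DEM cell size in metres (default 0.3).
#' @param params an [idw_params()].
#' @return A [raster_grid()].
#' @export
build_dem <- function(cloud, cell = 0.3, params = idw_params()) {
  stopifnot(inherits(cloud, "point_cloud"))
  g <- cloud$class == "ground"
  if (!any(g)) stop("cloud has no ground-classified points")
  geo <- .bbox_grid(cloud$x, cloud$y, cell)
  idw_interpolate(cloud$x[g], cloud$y[g], cloud$z[g], geo$origin, cell,
                  geo$nrow, geo$ncol, params)
}

#' Build a digital surface model from first returns
#'
#' IDW interpolation of all first returns (the canopy surface where trees
#' are present, bare ground elsewhere).
#'
#' @inheritParams build_dem
#' @return A [raster_grid()].
#' @export
build_dsm <- function(cloud, cell = 0.3, params = idw_params()) {
  stopifnot(inherits(cloud, "point_cloud"))
  f <- cloud$return_number == 1L
  if (!any(f)) stop("cloud has no first returns")
  geo <- .bbox_grid(cloud$x, cloud$y, cell)
  idw_interpolate(cloud$x[f], cloud$y[f], cloud$z[f], geo$origin, cell,
                  geo$nrow, geo$ncol, params)
}

#' Conventional per-point normalization against a DEM
#'
#' The conventional normalized height of return j is
#' `h_j = z_j - DEM(x_j, y_j)` with the DEM sampled bilinearly. This is the
#' "before correction" height; on a slope it is biased by `-c tan(i)` for a
#' return a horizontal distance c upslope of its tree's base.
#'
#' @param cloud a [point_cloud()].
#' @param dem a [raster_grid()] covering the cloud extent.
#' @return Numeric vector of per-point heights (m); exactly invertible as
#'   `h + DEM(xy) = z`.
#' @export
conventional_normalize <- function(cloud, dem) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(dem, "raster_grid"))
  cloud$z - sample_surface(dem, cloud$x, cloud$y)
}

#' Grid normalized heights into a canopy height model
#'
#' IDW raster of normalized point heights (conventional or corrected).
#' Negative cells are permitted.
#'
#' @param x,y point coordinates (m).
#' @param heights normalized heights (m).
#' @param cell cell size (m), default 0.3.
#' @param params an [idw_params()].
#' @param geometry optional list with `origin`, `nrow`, `ncol` to force a
#'   grid geometry (for cellwise-comparable CHMs); default covers the
#'   points' bounding box padded by one cell.
#' @return A [raster_grid()].
#' @export
build_chm <- function(x, y, heights, cell = 0.3, params = idw_params(),
                      geometry = NULL) {
  if (length(x) == 0L) stop("no vegetation points")
  geo <- geometry %||% .bbox_grid(x, y, cell)
  idw_interpolate(x, y, heights, geo$origin, cell, geo$nrow, geo$ncol, params)
}
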