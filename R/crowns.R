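#' Crown polygon set
#'
#' A `crown_set` holds the closed, non-self-intersecting polygons that
#' delineate individual tree crowns. Each polygon has an id, one outer ring
#' and optional hole rings; rings are N x 2 coordinate matrices in metres
#' (not repeating the first vertex).
#'
#' @param polygons list of polygons; each polygon is a list with elements
#'   `id` and `rings` (list of N x 2 matrices; attribute `hole` marks holes).
#' @return An object of class `crown_set`.
#' @export
crown_set <- function(polygons = list()) {
  for (p in polygons) {
    for (ring in p$rings) {
      if (!is.matrix(ring) || ncol(ring) != 2L || nrow(ring) < 3L)
        stop("crown ", p$id, ": each ring must be an N x 2 matrix, N >= 3")
      if (cpp_ring_self_intersects(ring[, 1], ring[, 2]))
        stop("crown ", p$id, ": self-intersecting ring")
      if (abs(.ring_area(ring)) <= 0)
        stop("crown ", p$id, ": zero-area ring")
    }
  }
  structure(list(polygons = polygons), class = "crown_set")
}

#' @export
print.crown_set <- function(x, ...) {
  cat(sprintf("<crown_set> %d crown polygon(s)\n", length(x$polygons)))
  if (length(x$polygons))
    cat(sprintf("  total area %.1f m2\n", sum(crown_areas(x))))
  invisible(x)
}

#' @export
length.crown_set <- function(x) length(x$polygons)

# signed shoelace area of an open ring
.ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Crown polygon areas
#'
#' @param crowns a [crown_set()].
#' @return Numeric vector of areas in square metres (holes subtracted).
#' @export
crown_areas <- function(crowns) {
  stopifnot(inherits(crowns, "crown_set"))
  vapply(crowns$polygons, function(p) {
    sum(vapply(p$rings, function(r) {
      a <- abs(.ring_area(r))
      if (isTRUE(attr(r, "hole"))) -a else a
    }, 0))
  }, 0)
}

#' Crown ids
#' @param crowns a [crown_set()].
#' @return Vector of polygon ids.
#' @export
crown_ids <- function(crowns) {
  unlist(lapply(crowns$polygons, function(p) p$id))
}

# containment codes for one polygon: 0 out, 1 in, 2 on boundary
.crown_contains <- function(poly, x, y, eps = 1e-9) {
  status <- rep(0L, length(x))
  for (ring in poly$rings) {
    s <- cpp_point_in_ring(x, y, ring[, 1], ring[, 2], eps)
    if (isTRUE(attr(ring, "hole"))) {
      status[s == 1L & status == 1L] <- 0L   # inside a hole
      status[s == 2L] <- 2L                  # hole boundary counts as boundary
    } else {
      status[s == 1L & status == 0L] <- 1L
      status[s == 2L] <- 2L
    }
  }
  status
}

.close_ring <- function(m) {
  # drop a repeated closing vertex if present
  if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

#' Read crown polygons from GeoJSON
#'
#' Accepts a FeatureCollection (or bare geometry) of Polygon / MultiPolygon
#' features in projected metre coordinates. Feature ids are taken from the
#' GeoJSON `id` member (or an `id` property) and otherwise assigned
#' sequentially. Rings are validated: closed, non-self-intersecting,
#' positive area; a self-intersecting ring raises an error naming the
#' feature id.
#'
#' @param path GeoJSON file.
#' @return A [crown_set()].
#' @export
read_crowns <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- switch(gj$type %||% "",
    FeatureCollection = gj$features,
    Feature = list(gj),
    Polygon = ,
    MultiPolygon = list(list(type = "Feature", geometry = gj, properties = NULL)),
    stop("not a GeoJSON FeatureCollection/Feature/Polygon: ", path))
  polys <- list()
  next_id <- 1L
  for (f in feats) {
    id <- f$id %||% f$properties$id %||% next_id
    if (is.numeric(id)) next_id <- max(next_id, as.integer(id) + 1L) else next_id <- next_id + 1L
    geom <- f$geometry
    ringsets <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("feature ", id, ": unsupported geometry type ", geom$type))
    rings <- list()
    for (rs in ringsets) {
      for (k in seq_along(rs)) {
        m <- do.call(rbind, lapply(rs[[k]], function(v) as.numeric(v[1:2])))
        m <- .close_ring(m)
        if (nrow(m) < 3L) stop("feature ", id, ": ring with fewer than 3 vertices")
        if (cpp_ring_self_intersects(m[, 1], m[, 2]))
          stop("feature ", id, ": self-intersecting ring")
        if (abs(.ring_area(m)) <= 0) stop("feature ", id, ": zero-area ring")
        attr(m, "hole") <- k > 1L
        rings[[length(rings) + 1L]] <- m
      }
    }
    polys[[length(polys) + 1L]] <- list(id = id, rings = rings)
  }
  crown_set(polys)
}

#' Write crown polygons as GeoJSON
#'
#' @param crowns a [crown_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_crowns <- function(crowns, path) {
  stopifnot(inherits(crowns, "crown_set"))
  feats <- lapply(crowns$polygons, function(p) {
    outer <- Filter(function(r) !isTRUE(attr(r, "hole")), p$rings)
    holes <- Filter(function(r) isTRUE(attr(r, "hole")), p$rings)
    ring2coords <- function(m) {
      m <- rbind(m, m[1L, ])                      # GeoJSON rings are closed
      lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
    }
    coords <- c(lapply(outer, ring2coords), lapply(holes, ring2coords))
    list(type = "Feature", id = p$id,
         properties = list(id = p$id),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
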