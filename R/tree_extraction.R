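#' Detect tree apices as CHM local maxima
#'
#' A cell is an apex if it is at least `min_height` and strictly exceeds
#' every other cell of the square window centred on it; exactly tied
#' plateaus have no strict maximum and yield no apex (a flat CHM detects
#' nothing).
#'
#' @param chm a [raster_grid()] canopy height model.
#' @param min_height minimum apex height (m), default 1.8.
#' @param window square window size in metres (default 3); must span at
#'   least 3 cells and no more than the raster.
#' @return Data frame with `x`, `y` (cell centres), `height`, `row`, `col`,
#'   ordered by decreasing height.
#' @export
detect_apices <- function(chm, min_height = 1.8, window = 3) {
  stopifnot(inherits(chm, "raster_grid"))
  v <- chm$values
  hw <- max(1L, as.integer(round(window / 2 / chm$cell)))
  if (2L * hw + 1L > min(dim(v)))
    stop("window (", 2 * hw + 1, " cells) larger than raster")
  nr <- nrow(v); nc <- ncol(v)
  out <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      z <- v[r, c]
      if (is.na(z) || z < min_height) next
      rr <- max(1L, r - hw):min(nr, r + hw)
      cc <- max(1L, c - hw):min(nc, c + hw)
      win <- v[rr, cc]
      win[match(r, rr), match(c, cc)] <- NA     # exclude the cell itself
      if (all(is.na(win))) next
      if (z <= max(win, na.rm = TRUE)) next     # strict: ties are not apices
      out[[length(out) + 1L]] <- c(r, c, z)
    }
  }
  if (!length(out))
    return(data.frame(x = numeric(0), y = numeric(0), height = numeric(0),
                      row = integer(0), col = integer(0)))
  m <- do.call(rbind, out)
  res <- data.frame(x = chm$origin[1] + (m[, 2] - 1) * chm$cell,
                    y = chm$origin[2] + (m[, 1] - 1) * chm$cell,
                    height = m[, 3], row = as.integer(m[, 1]),
                    col = as.integer(m[, 2]))
  res[order(-res$height), , drop = FALSE]
}

#' Marker-based watershed crown segmentation of a CHM
#'
#' Grows crown regions from the apex seeds over the inverted CHM: cells are
#' flooded in order of decreasing height, each masked cell joining the
#' region of the highest neighbour that reaches it first, restricted to
#' cells at or above `min_height` and 4-connected to their apex.
#'
#' @param chm a [raster_grid()].
#' @param apices data frame from [detect_apices()] (needs `row`, `col`;
#'   labels are `seq_len(nrow(apices))`).
#' @param min_height mask threshold (m), default 1.8.
#' @return A [raster_grid()] of integer crown labels (nodata outside the
#'   mask and in unreached cells); label regions partition the mask cells
#'   reachable from the seeds, one region per apex.
#' @export
segment_crowns_watershed <- function(chm, apices, min_height = 1.8) {
  stopifnot(inherits(chm, "raster_grid"))
  if (nrow(apices) < 1L) stop("need at least one apex")
  v <- chm$values
  mask <- !is.na(v) & v >= min_height
  lab <- cpp_marker_watershed(v, mask,
                              as.integer(apices$row - 1L),
                              as.integer(apices$col - 1L),
                              seq_len(nrow(apices)))
  g <- raster_grid(lab, origin = chm$origin, cell = chm$cell)
  g$values <- lab     # keep integer storage
  g
}

#' Compare two apex detections
#'
#' Greedy nearest-neighbour matching: repeatedly pairs the globally closest
#' unmatched apices within `radius` metres.
#'
#' @param det_a,det_b data frames with `x`, `y` (and optionally `height`).
#' @param radius maximum match distance (m), default 2.
#' @return A list with counts of both detections, the matched pairs
#'   (indices into each input and pair distance), the unmatched indices and
#'   summary distances (`mean_dist`, `max_dist`).
#' @export
compare_extractions <- function(det_a, det_b, radius = 2) {
  na <- nrow(det_a); nb <- nrow(det_b)
  pairs <- data.frame(a = integer(0), b = integer(0), dist = numeric(0))
  if (na > 0L && nb > 0L) {
    d <- outer(seq_len(na), seq_len(nb), function(i, j)
      sqrt((det_a$x[i] - det_b$x[j])^2 + (det_a$y[i] - det_b$y[j])^2))
    repeat {
      m <- which.min(d)
      if (!length(m) || d[m] > radius || !is.finite(d[m])) break
      i <- (m - 1L) %% na + 1L
      j <- (m - 1L) %/% na + 1L
      pairs <- rbind(pairs, data.frame(a = i, b = j, dist = d[m]))
      d[i, ] <- Inf
      d[, j] <- Inf
    }
  }
  list(n_a = na, n_b = nb, matched = pairs,
       unmatched_a = setdiff(seq_len(na), pairs$a),
       unmatched_b = setdiff(seq_len(nb), pairs$b),
       mean_dist = if (nrow(pairs)) mean(pairs$dist) else NA_real_,
       max_dist = if (nrow(pairs)) max(pairs$dist) else NA_real_)
}
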