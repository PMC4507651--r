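#' Regular raster grid
#'
#' A `raster_grid` stores a regular, axis-aligned grid of values (metres for
#' DEM/DSM/CHM surfaces). The origin is the coordinate of the **lower-left
#' cell centre**; `values` is an `nrow x ncol` matrix with row 1 the
#' southernmost row (y increases with row index) and missing cells stored as
#' `NA` (never mixed into arithmetic).
#'
#' @param values numeric matrix (`nrow` rows = y, `ncol` cols = x).
#' @param origin length-2 numeric, (x, y) of the lower-left cell centre.
#' @param cell cell size in metres (> 0), default 0.3.
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(0, 4, 5), origin = c(100, 200), cell = 0.5)
#' dim(g$values)
#' @export
raster_grid <- function(values, origin = c(0, 0), cell = 0.3) {
  values <- as.matrix(values)
  if (!is.numeric(cell) || length(cell) != 1L || !is.finite(cell) || cell <= 0)
    stop("cell size must be a single positive number")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("origin must be a finite (x, y) pair")
  storage.mode(values) <- "double"
  structure(list(values = values, origin = as.numeric(origin), cell = cell),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells @ %g m, origin (%.2f, %.2f)\n",
              nrow(v), ncol(v), x$cell, x$origin[1], x$origin[2]))
  if (any(is.finite(v)))
    cat(sprintf("  values: [%.3f, %.3f], %d nodata cells\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

# cell-centre coordinate vectors
.grid_x <- function(g) g$origin[1] + (seq_len(ncol(g$values)) - 1L) * g$cell
.grid_y <- function(g) g$origin[2] + (seq_len(nrow(g$values)) - 1L) * g$cell

.ascii_nodata <- -9999

#' Write a raster grid to disk
#'
#' `esri-ascii` writes a plain-text ESRI ASCII grid (`xllcenter` convention,
#' nodata -9999) that round-trips exactly at the written precision.
#' `geotiff` writes a 32-bit TIFF whose values are affinely rescaled to the
#' unit range, an ESRI world file (`.tfw`) for georeferencing-aware GIS
#' software, and a GDAL-style JSON sidecar (`.aux.json`) holding the value
#' scaling and grid geometry; [read_raster()] restores values to within
#' 32-bit float precision of the value range.
#'
#' @param grid a [raster_grid()].
#' @param path output file.
#' @param format `"esri-ascii"` or `"geotiff"`.
#' @param digits decimal digits for ASCII output.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, format = c("esri-ascii", "geotiff"),
                         digits = 6) {
  stopifnot(inherits(grid, "raster_grid"))
  format <- match.arg(format)
  v <- grid$values
  if (format == "esri-ascii") {
    con <- try(file(path, "w"), silent = TRUE)
    if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
    on.exit(close(con))
    writeLines(c(sprintf("ncols %d", ncol(v)),
                 sprintf("nrows %d", nrow(v)),
                 sprintf("xllcenter %.10g", grid$origin[1]),
                 sprintf("yllcenter %.10g", grid$origin[2]),
                 sprintf("cellsize %.10g", grid$cell),
                 sprintf("NODATA_value %d", .ascii_nodata)), con)
    vv <- v
    vv[is.na(vv)] <- .ascii_nodata
    # ASCII grids run north -> south
    for (r in rev(seq_len(nrow(vv))))
      writeLines(paste(formatC(vv[r, ], format = "f", digits = digits),
                       collapse = " "), con)
  } else {
    lo <- suppressWarnings(min(v, na.rm = TRUE))
    hi <- suppressWarnings(max(v, na.rm = TRUE))
    if (!is.finite(lo)) { lo <- 0; hi <- 1 }
    if (hi <= lo) hi <- lo + 1
    sc <- (v - lo) / (hi - lo)
    sc[is.na(sc)] <- 0
    nav <- is.na(v) * 1.0
    # channel 1 scaled values, channel 2 nodata mask; rows north -> south
    arr <- array(0, c(nrow(v), ncol(v), 2))
    arr[, , 1] <- sc[rev(seq_len(nrow(v))), , drop = FALSE]
    arr[, , 2] <- nav[rev(seq_len(nrow(v))), , drop = FALSE]
    ok <- try(tiff::writeTIFF(arr, path, bits.per.sample = 32L),
              silent = TRUE)
    if (inherits(ok, "try-error")) stop("cannot write TIFF: ", path)
    jsonlite::write_json(list(origin = grid$origin, cell = grid$cell,
                              lo = lo, hi = hi),
                         paste0(path, ".aux.json"), auto_unbox = TRUE,
                         digits = NA)
    # world file: cell size, rotation, centre of upper-left pixel
    tfw <- sub("\\.[^.]+$", ".tfw", path)
    writeLines(formatC(c(grid$cell, 0, 0, -grid$cell, grid$origin[1],
                         grid$origin[2] + (nrow(v) - 1) * grid$cell),
                       format = "g", digits = 12), tfw)
  }
  invisible(path)
}

#' Read a raster grid from disk
#'
#' Reads the two formats written by [write_raster()].
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"esri-ascii"` or `"geotiff"`.
#' @return A [raster_grid()].
#' @export
read_raster <- function(path, format = c("auto", "esri-ascii", "geotiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "geotiff"
              else "esri-ascii"
  if (format == "esri-ascii") {
    lines <- readLines(path, warn = FALSE)
    hdr <- list()
    i <- 1L
    while (grepl("^[A-Za-z]", lines[i])) {
      kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
      i <- i + 1L
    }
    nc <- hdr$ncols; nr <- hdr$nrows
    if (is.null(nc) || is.null(nr)) stop("not an ESRI ASCII grid: ", path)
    cell <- hdr$cellsize
    ox <- if (!is.null(hdr$xllcenter)) hdr$xllcenter else hdr$xllcorner + cell / 2
    oy <- if (!is.null(hdr$yllcenter)) hdr$yllcenter else hdr$yllcorner + cell / 2
    nod <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else .ascii_nodata
    body <- scan(text = lines[i:length(lines)], quiet = TRUE)
    if (length(body) != nr * nc) stop("ASCII grid body has wrong cell count")
    v <- matrix(body, nr, nc, byrow = TRUE)[rev(seq_len(nr)), , drop = FALSE]
    v[v == nod] <- NA_real_
    raster_grid(v, origin = c(ox, oy), cell = cell)
  } else {
    aux <- paste0(path, ".aux.json")
    if (!file.exists(aux)) stop("missing sidecar ", aux)
    arr <- suppressWarnings(tiff::readTIFF(path))
    meta <- jsonlite::fromJSON(aux)
    nr <- dim(arr)[1L]
    sc <- arr[, , 1][rev(seq_len(nr)), , drop = FALSE]
    nav <- arr[, , 2][rev(seq_len(nr)), , drop = FALSE]
    v <- meta$lo + sc * (meta$hi - meta$lo)
    v[nav > 0.5] <- NA_real_
    raster_grid(v, origin = meta$origin, cell = meta$cell)
  }
}

#' Sample a raster surface at arbitrary coordinates
#'
#' Bilinear interpolation of the four surrounding cell centres; beyond the
#' outermost cell centres (but within the half-cell margin of the grid
#' extent) the edge value is carried outward. If some of the four
#' surrounding cells are nodata, the interpolation weights are renormalized
#' over the valid cells; if all four are nodata, or a coordinate is outside
#' the grid extent, an error is raised.
#'
#' @param grid a [raster_grid()].
#' @param x,y numeric coordinate vectors (metres).
#' @return Numeric vector of sampled values.
#' @export
sample_surface <- function(grid, x, y) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v); cs <- grid$cell
  if (length(y) != length(x)) stop("x and y must have equal length")
  gx <- (x - grid$origin[1]) / cs
  gy <- (y - grid$origin[2]) / cs
  out_ext <- gx < -0.5 | gx > nc - 0.5 | gy < -0.5 | gy > nr - 0.5
  if (any(out_ext))
    stop("coordinate outside raster extent at index ",
         paste(utils::head(which(out_ext), 5L), collapse = ", "))
  c0 <- pmin(pmax(floor(gx), 0), nc - 2L)
  r0 <- pmin(pmax(floor(gy), 0), nr - 2L)
  fx <- pmin(pmax(gx - c0, 0), 1)
  fy <- pmin(pmax(gy - r0, 0), 1)
  idx <- function(r, c) v[cbind(r + 1L, c + 1L)]
  vals <- cbind(idx(r0, c0), idx(r0, c0 + 1L), idx(r0 + 1L, c0),
                idx(r0 + 1L, c0 + 1L))
  w <- cbind((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  w[is.na(vals)] <- 0
  vals[is.na(vals)] <- 0
  sw <- rowSums(w)
  if (any(sw == 0))
    stop("all four neighbouring cells are nodata at index ",
         paste(utils::head(which(sw == 0), 5L), collapse = ", "))
  rowSums(w * vals) / sw
}

#' Cellwise difference of two aligned rasters
#'
#' Computes `a - b` where both grids are non-nodata; any cell that is nodata
#' in either input is nodata in the result. The grids must share geometry.
#'
#' @param a,b [raster_grid()] objects with identical origin, cell and shape.
#' @return A [raster_grid()].
#' @export
raster_difference <- function(a, b) {
  stopifnot(inherits(a, "raster_grid"), inherits(b, "raster_grid"))
  if (!isTRUE(all.equal(a$origin, b$origin)) || a$cell != b$cell ||
      !all(dim(a$values) == dim(b$values)))
    stop("rasters are not aligned")
  raster_grid(a$values - b$values, origin = a$origin, cell = a$cell)
}
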