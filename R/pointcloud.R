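#' LiDAR point cloud container
#'
#' A `point_cloud` is a data frame with columns `x`, `y`, `z` (metres, in a
#' projected planar CRS), `return_number` (integer >= 1) and `class` (one of
#' `"unclassified"`, `"ground"`, `"vegetation"`). Coordinates must be finite
#' and at least one point is required.
#'
#' @param x,y,z numeric coordinate vectors (metres).
#' @param return_number integer return numbers (>= 1); recycled.
#' @param class character class labels; recycled.
#' @return An object of class `point_cloud` (also a `data.frame`).
#' @examples
#' pc <- point_cloud(runif(10), runif(10), runif(10, 0, 20))
#' nrow(pc)
#' @export
point_cloud <- function(x, y, z, return_number = 1L, class = "unclassified") {
  n <- length(x)
  if (n == 0L) stop("point cloud must contain at least one point")
  if (length(y) != n || length(z) != n)
    stop("x, y and z must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("point coordinates must be finite")
  return_number <- as.integer(rep_len(return_number, n))
  if (any(is.na(return_number)) || any(return_number < 1L))
    stop("return_number must be an integer >= 1")
  class <- rep_len(as.character(class), n)
  bad <- !class %in% c("unclassified", "ground", "vegetation")
  if (any(bad))
    stop("unknown class label(s): ", paste(unique(class[bad]), collapse = ", "))
  pc <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   return_number = return_number, class = class,
                   stringsAsFactors = FALSE)
  structure(pc, class = c("point_cloud", "data.frame"))
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points\n", nrow(x)))
  cat(sprintf("  x: [%.2f, %.2f]  y: [%.2f, %.2f]  z: [%.2f, %.2f] m\n",
              min(x$x), max(x$x), min(x$y), max(x$y), min(x$z), max(x$z)))
  tb <- table(x$class)
  cat("  classes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

# ASPRS-style class codes used in xyz-text column 5
.class_to_code <- function(class) {
  c(unclassified = 1L, ground = 2L, vegetation = 5L)[class]
}
.code_to_class <- function(code) {
  out <- rep("unclassified", length(code))
  out[code == 2] <- "ground"
  out[code %in% c(3, 4, 5)] <- "vegetation"
  out
}

#' Read a point cloud from disk
#'
#' Supports whitespace- or comma-delimited text with columns
#' `x y z [return_number] [class_code]` (header lines starting with `#` are
#' skipped; a missing return number defaults to 1 and a missing class to
#' unclassified; class codes follow ASPRS usage, 2 = ground, 3-5 =
#' vegetation). LAS/LAZ requires an external LAS backend, which this package
#' does not bundle; `format = "las"` therefore raises an informative error
#' and the text format is the supported interchange path.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"xyz"` or `"las"`.
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "las")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.la[sz]$", path, ignore.case = TRUE)) "las" else "xyz"
  if (format == "las")
    stop("no LAS backend is available; convert to xyz text (x y z [return] [class])")

  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty point file: ", path)
  toks <- strsplit(trimws(lines), "[[:space:],]+")
  nf <- lengths(toks)
  if (any(nf < 3L))
    stop("malformed row at line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 columns")
  ncol <- min(nf)
  m <- matrix(NA_real_, length(toks), ncol)
  for (j in seq_len(ncol)) {
    v <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", j)))
    if (anyNA(v))
      stop("malformed row at line ", lineno[which(is.na(v))[1L]],
           ": non-numeric value in column ", j)
    m[, j] <- v
  }
  point_cloud(m[, 1], m[, 2], m[, 3],
              return_number = if (ncol >= 4) as.integer(m[, 4]) else 1L,
              class = if (ncol >= 5) .code_to_class(m[, 5]) else "unclassified")
}

#' Write a point cloud as xyz text
#'
#' Writes `x y z return_number class_code` rows (space-delimited, ASPRS-style
#' class codes) preceded by a `#` header line. The file round-trips through
#' [read_point_cloud()].
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @param digits number of significant digits (default preserves 1e-3 m).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, digits = 6) {
  stopifnot(inherits(cloud, "point_cloud"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# x y z return class", con)
  writeLines(sprintf("%.*f %.*f %.*f %d %d",
                     digits, cloud$x, digits, cloud$y, digits, cloud$z,
                     cloud$return_number, .class_to_code(cloud$class)), con)
  invisible(path)
}
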