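#' Terrain-induced bias of a conventionally normalized return
#'
#' On a uniform slope of angle i, a canopy return a signed horizontal
#' distance c from the trunk along the upslope direction has its
#' conventional (per-point DEM-subtracted) height biased by `-c tan(i)`:
#' upslope returns are depressed, downslope returns elevated.
#'
#' @param offset signed horizontal distance from the trunk (m), positive
#'   upslope.
#' @param slope_deg slope angle in degrees, |slope| < 90.
#' @return Bias in metres (antisymmetric in `offset`).
#' @examples
#' point_bias(2, 45)   # -2: a return 2 m upslope is depressed by 2 m
#' @export
point_bias <- function(offset, slope_deg) {
  if (any(abs(slope_deg) >= 90)) stop("|slope_deg| must be < 90")
  -offset * tan(slope_deg * pi / 180)
}

#' Maximum terrain-induced canopy height difference
#'
#' The largest conventional-normalization error over a crown of diameter d
#' on a slope of angle i occurs at the crown edge along the slope direction
#' and equals `(d/2) tan(i)`.
#'
#' @param crown_diameter crown diameter d (m), > 0.
#' @param slope_deg slope angle i in degrees, in `[0, 90)`.
#' @return Maximum height difference in metres.
#' @examples
#' max_difference(10, 20)  # 1.82 m
#' @export
max_difference <- function(crown_diameter, slope_deg) {
  if (any(crown_diameter <= 0)) stop("crown_diameter must be positive")
  if (any(slope_deg < 0) || any(slope_deg >= 90))
    stop("slope_deg must be in [0, 90)")
  crown_diameter / 2 * tan(slope_deg * pi / 180)
}

#' Grid of maximum canopy height differences
#'
#' Evaluates [max_difference()] over a grid of crown diameters and slope
#' gradients. The defaults span the crown sizes (3-15 m) and slopes
#' (5-50 degrees) typical of steep forested terrain.
#'
#' @param diameters crown diameters (m).
#' @param slopes slope angles (degrees).
#' @return Numeric matrix (rows = diameters, columns = slopes), with
#'   dimnames.
#' @examples
#' round(max_difference_table(), 2)
#' @export
max_difference_table <- function(diameters = c(3, 5, 10, 15),
                                 slopes = c(5, 10, 20, 30, 40, 50)) {
  if (length(diameters) == 0L || length(slopes) == 0L)
    stop("diameters and slopes must be non-empty")
  m <- outer(diameters, slopes, max_difference)
  dimnames(m) <- list(crown_d_m = diameters, slope_deg = slopes)
  m
}
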