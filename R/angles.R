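#' Wrap an angle into [0, 360)
#'
#' Colour hue and dot location are both represented as angles on a circular
#' space measured in degrees.  `wrap_angle()` maps any finite angle onto the
#' canonical interval `[0, 360)`.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length with values in `[0, 360)`.
#' @examples
#' wrap_angle(c(0, 365, -90))
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("wrap_angle(): angles must be finite numeric values", call. = FALSE)
  }
  x %% 360
}

#' Signed circular distance between two angles
#'
#' Returns the signed angular difference `a - b` mapped into `(-180, 180]`.
#' The unsigned recall error used throughout is `abs(circ_dist(...))`.  An
#' exactly antipodal pair resolves deterministically to `+180`.
#'
#' @param a,b Numeric vectors of angles in degrees (recycled).
#' @return Signed difference in degrees, in `(-180, 180]`.
#' @examples
#' circ_dist(10, 350)   # 20
#' circ_dist(0, 180)    # 180 by convention
#' @export
circ_dist <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(a)) || any(!is.finite(b))) {
    stop("circ_dist(): angles must be finite numeric values", call. = FALSE)
  }
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# degree/radian conversion is owned here; density code works in radians
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
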