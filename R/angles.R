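#' Angular helpers for axial (180-degree periodic) orientation data
#'
#' Orientations are axial: a line at 0 degrees is the same line as one at 180
#' degrees, so all absolute orientations live in the half-open interval
#' \[0, 180) and all signed differences in (-90, 90]. Throughout the package a
#' positive signed offset means "more clockwise"; distribution supports use the
#' same convention, so negative support offsets point counter-clockwise.
#'
#' @param theta numeric vector of orientations in degrees.
#' @return `wrap_orientation()` returns orientations wrapped into \[0, 180).
#' @examples
#' wrap_orientation(c(-10, 185, 90))
#' signed_offset(5, 175)   # 10: seam wrap
#' axial_distance(0, 170)  # 10
#' @export
wrap_orientation <- function(theta) {
  theta %% 180
}

#' @rdname wrap_orientation
#' @param a,b orientations in degrees (any real values; wrapped axially).
#' @return `signed_offset()` returns the unique axial difference `a - b`
#'   wrapped into (-90, 90]; positive values mean `a` is clockwise of `b`.
#' @export
signed_offset <- function(a, b) {
  d <- (a - b) %% 180
  ifelse(d > 90, d - 180, d)
}

#' @rdname wrap_orientation
#' @return `axial_distance()` returns the unsigned axial distance in
#'   \[0, 90].
#' @export
axial_distance <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
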