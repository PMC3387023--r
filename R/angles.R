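#' Orientation space conversions
#'
#' Physical orientations live on \[-90, 90) degrees (an orientation is
#' identified with itself plus 180 degrees).  Internally the package doubles
#' the angle: physical degrees map linearly onto \[-pi, pi) radians, which
#' makes the orientation circle an ordinary 2*pi-periodic circle on which
#' von Mises distributions and circular distances are standard.
#'
#' @param deg physical orientations in degrees (any real values; wrapped
#'   into \[-90, 90)).
#' @param rad internal angles in radians (wrapped into \[-pi, pi)).
#' @return `deg_to_internal` returns internal radians in \[-pi, pi);
#'   `internal_to_deg` returns physical degrees in \[-90, 90).
#' @examples
#' deg_to_internal(c(-90, 0, 45))
#' internal_to_deg(pi / 2)
#' @export
deg_to_internal <- function(deg) {
  wrap_internal(deg * pi / 90)
}

#' @rdname deg_to_internal
#' @export
internal_to_deg <- function(rad) {
  wrap_internal(rad) * 90 / pi
}

#' @rdname deg_to_internal
#' @export
wrap_internal <- function(rad) {
  ((rad + pi) %% (2 * pi)) - pi
}

#' Circular distance in internal space
#'
#' Absolute angular distance between two internal angles, in \[0, pi\].
#'
#' @param a,b internal angles in radians.
#' @return non-negative distances.
#' @examples
#' circ_dist(-3, 3) # short way around
#' @export
circ_dist <- function(a, b) {
  abs(wrap_internal(a - b))
}
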