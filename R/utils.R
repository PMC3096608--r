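#' @keywords internal
#' @useDynLib pseudotax, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles into (-180, 180]
#'
#' @param theta angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @export
wrap_angle <- function(theta) {
  w <- theta %% 360
  w[w > 180] <- w[w > 180] - 360
  # map -180 to +180 so the interval is half-open as documented
  w[w == -180] <- 180
  w
}

#' Signed circular difference a - b in degrees, wrapped to (-180, 180]
#' @param a,b angles in degrees.
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Unit vector pointing at an angle
#' @param theta angle in degrees CCW from +x.
#' @return length-2 numeric vector.
#' @export
unit_vector <- function(theta) c(cos(deg2rad(theta)), sin(deg2rad(theta)))

vec_angle <- function(v) rad2deg(atan2(v[2], v[1]))
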