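#' Signed circular difference between two hue angles
#'
#' Computes the signed shortest arc from `b` to `a` on the 360-degree hue
#' circle. This is the canonical convention used throughout the package for
#' target-response errors: positive values mean `a` lies counter-clockwise
#' of `b`.
#'
#' @param a,b Hue angles in degrees. Recycled to a common length.
#' @return Signed difference in degrees, in the half-open interval
#'   \code{(-180, 180]}.
#' @examples
#' circular_difference(10, 350)   # +20, across the wrap
#' circular_difference(200, 10)   # -170
#' @export
circular_difference <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(a)) || any(!is.finite(b))) {
    stop("circular_difference() requires finite numeric angles", call. = FALSE)
  }
  wrap_signed(a - b)
}

#' Wrap angles to the signed interval (-180, 180]
#'
#' @param x Angles in degrees.
#' @return Angles wrapped to \code{(-180, 180]}.
#' @export
wrap_signed <- function(x) {
  d <- (x + 180) %% 360 - 180
  # %% maps exact -180 to -180; convention puts the boundary at +180
  d[d == -180] <- 180
  d
}

#' Wrap angles to [0, 360)
#'
#' @param x Angles in degrees.
#' @return Angles wrapped to \code{[0, 360)}.
#' @export
wrap_positive <- function(x) x %% 360

#' Absolute circular distance in degrees
#'
#' @param a,b Hue angles in degrees.
#' @return Distance in \code{[0, 180]}.
#' @export
circular_distance <- function(a, b) abs(wrap_signed(a - b))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Mean resultant length and circular mean
#'
#' @param x Angles in degrees.
#' @param w Optional non-negative weights.
#' @return List with `mean` (degrees, in (-180, 180]) and `R` (mean
#'   resultant length in [0, 1]).
#' @keywords internal
circ_mean_resultant <- function(x, w = NULL) {
  th <- deg2rad(x)
  if (is.null(w)) w <- rep(1, length(th))
  s <- sum(w * sin(th))
  c_ <- sum(w * cos(th))
  n <- sum(w)
  list(mean = rad2deg(atan2(s, c_)), R = sqrt(s^2 + c_^2) / n)
}
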