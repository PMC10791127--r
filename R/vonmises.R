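#' Von Mises density on the hue circle
#'
#' Density of the von Mises distribution evaluated at angles in degrees.
#' The concentration `kappa` is defined on the radian scale, as usual; the
#' returned density is per radian unless `per_degree = TRUE`.
#'
#' @param x Angles in degrees.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration parameter (> 0 for a proper unimodal density;
#'   `kappa = 0` gives the circular uniform).
#' @param per_degree If `TRUE`, return density per degree (divided by
#'   180/pi) so that it integrates to 1 over a 360-degree support.
#' @return Density values.
#' @export
dvonmises <- function(x, mu = 0, kappa = 1, per_degree = FALSE) {
  stopifnot(kappa >= 0)
  th <- deg2rad(wrap_signed(x - mu))
  # exp-scaled Bessel keeps this finite for very large kappa
  dens <- exp(kappa * (cos(th) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
  if (per_degree) dens <- dens * pi / 180
  dens
}

#' Draw von Mises random angles
#'
#' Best-Fisher rejection sampler. Draws are returned in degrees wrapped to
#' \code{(-180, 180]} around `mu`.
#'
#' @param n Number of draws.
#' @param mu Mean direction, degrees.
#' @param kappa Concentration (radian scale).
#' @param seed Optional integer seed; when supplied the draw is
#'   reproducible and the caller's RNG state is untouched.
#' @return Numeric vector of angles in degrees.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, rvonmises(n, mu, kappa)))
  }
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) {
    return(wrap_signed(stats::runif(n, -180, 180) + mu))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(32L, ceiling((n - length(out)) * 1.5))
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, th)
  }
  wrap_signed(rad2deg(out[seq_len(n)]) + mu)
}

# A1(kappa) = I1(kappa)/I0(kappa), the mean resultant length of a von Mises
a1_ratio <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Invert A1 by the Best-Fisher piecewise approximation plus Newton steps.
a1_inv <- function(R, newton_steps = 5L) {
  if (R <= 0) return(0)
  R <- min(R, 1 - 1e-12)
  k <- if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
  for (i in seq_len(newton_steps)) {
    A <- a1_ratio(k)
    dA <- 1 - A^2 - A / k
    if (!is.finite(dA) || dA <= 0) break
    step <- (A - R) / dA
    k <- k - step
    if (!is.finite(k) || k <= 0) {
      k <- max(k, 1e-6)
      break
    }
    if (abs(step) < 1e-12 * max(1, k)) break
  }
  k
}
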